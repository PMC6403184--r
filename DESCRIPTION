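Package: minfa
Title: Predicting Motor-Imagery Neurofeedback Aptitude from White-Matter
    Fractional Anisotropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline linking EEG motor-imagery
    neurofeedback performance to diffusion-MRI white-matter structure.
    Implements the online neurofeedback signal chain (FIR and Butterworth
    band-pass filtering, artifact rejection, common spatial patterns,
    overlapping log band-power bins, cross-validated linear discriminant
    classifiers and the three-way BaseL/BaseR/LR performance score),
    atlas-region mean fractional-anisotropy extraction with an FA > 0.25
    mask, shrinkage linear discriminant analysis with correlation-adjusted
    t-score variable selection, repeated stratified cross-validation,
    Monte-Carlo permutation tests of cross-validation accuracy, and
    synthetic EEG and cohort generators so the whole chain is testable
    without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
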