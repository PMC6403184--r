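---
title: "Predicting motor-imagery neurofeedback aptitude from white-matter FA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting motor-imagery neurofeedback aptitude from white-matter FA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A substantial fraction of users cannot control a motor-imagery (MI)
brain-computer interface above the ~70% accuracy conventionally needed
for communication ("BCI inefficiency"). If aptitude could be predicted
from a stable anatomical measure — here, white-matter fractional
anisotropy (FA) from diffusion MRI — screening would not require an EEG
session at all. `minfa` implements the full analysis chain for that
question: score each subject's neurofeedback performance from EEG,
extract atlas-region FA, and test whether FA predicts a high/low
performance split.

The package has two halves:

1. **EEG half** — the online neurofeedback signal chain: band-pass
   filtering, epoching, artifact rejection, common spatial patterns
   (CSP), overlapping log band-power bins, three linear discriminant
   classifiers (baseline-vs-left `BaseL`, baseline-vs-right `BaseR`,
   left-vs-right `LR`), and the three performance percentages with their
   per-subject maximum and a cohort median split.
2. **Statistical half** — shrinkage linear discriminant analysis (SLDA)
   with correlation-adjusted t-score (CAT) variable selection, repeated
   stratified cross-validation, and a Monte-Carlo permutation test of
   the cross-validated accuracy.

Because cohort EEG + dMRI data of this kind are not freely
downloadable, both halves are exercised end-to-end on synthetic data
whose generators are first-class, tested package code.

# Performance scoring

Segments (1-s bins shifted by 62.5 ms; a 4-s epoch yields 49) are
classified and tallied per condition, with `C_x`/`T_x` the correct and
total counts:

$$\mathrm{BaseL} = 100\,\frac{C_B + C_{MILeft}}{T_B + T_{MILeft}},\qquad
  \mathrm{BaseR} = 100\,\frac{C_B + C_{MIRight}}{T_B + T_{MIRight}},\qquad
  \mathrm{LR} = 100\,\frac{C_{MILeft} + C_{MIRight}}{T_{MILeft} + T_{MIRight}}$$

Only the per-subject **maximum** of the three enters further analysis
(an upper estimate of each subject's controllable signal), and subjects
are labelled high/low by a median split (strictly-above-median = high;
for n = 21 this yields 11 low / 10 high). By default the baseline
denominator of each Base classifier uses only the matching side's
trials; `baseline_scope = "pooled"` switches to pooled baselines — the
source protocol does not pin this down, so it is a documented option.

# The EEG chain and its defaults

* **Filters.** Online path: 4th-order (prototype) Butterworth 8–30 Hz,
  causal in real time, forward–backward offline. A "0.5 dB pass-band
  ripple" is not a property a maximally-flat Butterworth can have; the
  implementation is maximally flat and the tests verify pass-band
  deviation ≤ 0.5 dB, which honours both the stated family and the
  stated tolerance. Offline cleaning path: zero-phase Hamming-window FIR
  (1–40 Hz). Independent-component cleaning is a human-in-the-loop step
  and is out of scope; bad channels are dropped, not interpolated,
  because synthetic montages carry no electrode geometry.
* **Epochs.** MI epochs at 0.5–4.5 s after MI onset; baseline epochs at
  −7 to −3 s. The baseline window is configurable because its printed
  specification ("-7–3 s") is typographically ambiguous; −7..−3 gives a
  4-s window matching the MI window and the 49-bin count.
* **Artifact rejection.** ±500 µV thresholding, then joint-probability
  rejection: per channel, the distribution of sample values across all
  epochs is estimated with a fixed 100-bin Laplace-smoothed histogram;
  an epoch is rejected when one channel's summed log-density deviates
  from the across-epoch mean by > 6 SD or the all-channel aggregate by
  > 2 SD, in a single pass. The histogram density is a reproducible
  stand-in for an unspecified toolbox internal. Re-running the
  joint-probability pass on its own output can reject further epochs
  (the global 2-SD rule re-centres); the thresholding pass is exactly
  idempotent.
* **CSP.** Per-epoch covariances are trace-normalized before class
  averaging (standard practice; makes the eigenvalues interpretable as
  variance fractions), a ridge of `1e-9 × trace` stabilizes short
  sessions, and filter signs are fixed so the largest pattern weight is
  positive, for reproducible serialization. Each side's candidate set is
  the three most extreme eigenvalues; the "neurophysiological
  plausibility" choice among them is a criterion hook whose default
  scores the absolute pattern weight on a configured motor-channel set,
  falling back to the most extreme eigenvalue.
* **Classifiers.** Fisher LDA with equal priors (the design is balanced,
  20 trials per hand). The feedback classifier is the *mean* of the
  seven fold models' weight vectors and biases — the most literal
  reading of "sevenfold cross-validation and the mean classifier";
  averaging posteriors instead would be a different (and unstated)
  choice.

# The prediction engine

`shrink_moments()` estimates class means plus James–Stein-type shrinkage
moments: the feature correlation matrix shrunk toward the identity and
the pooled variances toward their median, with analytic intensities of
the Schäfer–Strimmer family, clipped to [0, 1]. CAT scores decorrelate
the shrunk-variance t-scores:

$$\tau = (P^\ast)^{-1/2}\, t,\qquad
  t_j = \frac{\bar x_{1j} - \bar x_{2j}}{s^\ast_j\sqrt{1/n_1 + 1/n_2}}$$

with the inverse square root via symmetric eigendecomposition. Under an
identity correlation τ = t exactly; strongly correlated informative
features share their discriminative mass. Selection keeps features whose
mean |τ| across cross-validation folds exceeds 4. The absolute value
matters: a signed threshold would never admit negative-effect regions,
which the analysis design explicitly expects. Two numerical notes:

* Variance shrinkage toward the *median* is scale-sensitive, so τ is
  invariant to per-feature affine rescaling only with the variance
  intensity held fixed (common rescaling is always neutral). This is
  inherent to the median target, not an implementation artifact.
* On exactly-uncorrelated data the estimated correlation intensity does
  **not** vanish with n — the identity target is then the truth and
  shrinking fully is optimal. It vanishes when genuine correlation
  dominates estimation noise. The shrunk matrix approaches the identity
  either way.

`fit_slda()` rebuilds Σ* from the shrunk variances and correlations on
the selected features and applies the usual Gaussian discriminant with
empirical class priors. An empty selection falls back to predicting the
training-majority class, which keeps every permutation replicate
well-defined.

# Cross-validation and the permutation test

Accuracy is estimated by 10 repeats of stratified 5-fold CV with fresh
folds each repeat (whether the original analysis re-drew folds per
repeat is unstated; fresh folds are this package's recorded choice).
Selection is re-run inside *every* training split (5-fold within the
split), so no label ever influences the features available to predict
it. Fold assignment happens in a canonical content-based row order, so
accuracy at a fixed seed is invariant to row permutations of the table.

Significance comes from permuting the subjects' labels and re-running
the entire pipeline — selection included — 10,000 times by default. The
p-value is the literal proportion of permutations with accuracy ≥
observed (no +1 correction, matching the definition used in the source
analysis); p = 0 is therefore possible and printed as "< 1/n_perm". The
exact binomial tail `binomial_test()` is provided for comparison, since
binomial tests on CV accuracies are known to overstate significance.

**Calibration note.** With the CAT threshold at 4, *null* cohorts almost
never select any variable; the majority-class fallback then makes every
pipeline replicate output the same accuracy and the permutation p
degenerates to 1 — perfectly conservative (type-I error 0, never
anticonservative). The uniformity and type-I calibration checks
therefore run on the fixed-candidate ("variables selected: all") path,
which exercises the identical CV and permutation machinery with a
non-degenerate statistic; the selection path's conservatism is asserted
separately.

# Synthetic data: what it emulates, what it does not

**EEG generator.** Two sinusoidal mu-rhythm sources (default 11 Hz) with
slow multiplicative amplitude noise, mixed to the channels through fixed
C3/C4-like Gaussian spatial profiles, over 1/f channel noise. During MI
the contralateral source is attenuated by `1 − erd_depth` (event-related
desynchronization). The two sources get small opposite carrier offsets
(±0.35 Hz) and independent slow phase noise: two sources at an
*identical* frequency are mutually coherent, so their mixture's power
would depend on an arbitrary phase difference — no pair of real,
independent cortical generators behaves that way, and coherent sources
are also not separable by CSP. Defaults follow the emulated paradigm: 20
trials per hand, 500 Hz, 5-s baseline / 3-s cue / 5-s MI (so the trial
spans −8..+5 s around MI onset; a −5 s baseline start would leave the
−7..−3 s baseline epoch outside the trial), 0–4 s inter-trial jitter.
The ERD depth (0.5) and SNR (2) defaults are chosen for testability —
the source study reports no quantitative ERD magnitude. Not emulated:
volume conduction, ocular/cardiac artifacts, electrode geometry;
passing tests show the *chain* recovers injected lateralized ERD, not
that it would survive every real-world artifact.

**Cohort generator.** Each subject has a latent aptitude score
s ~ N(0,1), median-split into low/high. A region configured with effect
size d correlates with s by the ρ(d) that makes the realized
between-group Cohen's d converge to d (for a median split of a Gaussian,
d = cρ/√(1 − c²ρ²/4) with c = 2√(2/π); hence a per-region cap of
|d| ≲ 2.6). With several informative regions the requested correlations
can exceed what mutually independent regions can carry (two regions at
d = 1.5 already would), so the informative residuals are anti-correlated
near the feasibility bound, keeping the regions' mutual correlation as
small as the configured effect sizes permit (c ≈ 0.14 at d = 1.5 × 2).
The age–fornix coupling (target r = −0.49 over ages 48–77) is imposed by
mixing standardized age into that region's residual, which controls the
target correlation exactly in expectation. Covariates (education,
gender, handedness, verbal-fluency and trail-making scores) are drawn
from plausible older-adult marginals and are exchangeable via
`covariate_spec`; they carry no built-in signal.

**Volume fixtures.** Block-shaped atlas regions in ≤ 32³ volumes with a
deliberate fraction of voxels at or below the FA > 0.25 floor, for
exercising the strict-inequality masking rule. Registration and
tensor fitting are out of scope; volumes are born aligned.

# Problem sizes used in tests and the acceptance script

Simulation sizes are chosen so the full suite runs on one CPU in
minutes while keeping every Monte-Carlo margin interpretable: null-
calibration means over 50 cohorts (n = 40, all 48 regions); permutation
uniformity over 100 cohorts × 200 permutations with 2 CV repeats and a
10-region candidate set; recovery over 25 cohorts (d = 1.5 × 2 regions,
n = 40, full pipeline); the EEG chain over 10 simulated subjects
(16 channels, 40 trials per block, two blocks each). The permutation
uniformity check is necessarily approximate: with finitely many held-out
predictions the accuracy is discrete, ties make the p-value
super-uniform, and the KS distance reflects that granularity.

# Known limitations

* The selection threshold (mean |τ| > 4) is conservative at small
  effect sizes: at d = 1.5 and n = 40 the inner-fold t-scores sit near
  3.8, so selection fires in roughly half the training splits and the
  selection-path CV accuracy on such cohorts averages well below what
  the same cohorts support with a fixed candidate set. This mirrors the
  pipeline's real behavior — aggressive selection protects the null at
  the price of power — and is measured, not hidden, by the tests.
* The EDF writer/reader implements the minimal 16-bit subset of the
  format (one marker channel encodes events) — sufficient for
  round-tripping the package's own recordings, not a general EDF+
  implementation.
* Partial correlations are residual-based (each selected feature and
  the outcome residualized on the remaining selected features); whether
  the source analysis' reported partial correlations used exactly this
  definition is unknowable from the text, so the definition is
  documented rather than asserted as equivalent.
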