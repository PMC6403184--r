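#' Mean FA per atlas region
#'
#' For every requested region label, the mean fractional anisotropy over
#' the voxels carrying that label AND exceeding the FA floor (strictly:
#' `FA > fa_floor`, default 0.25). Regions with no qualifying voxel — the
#' label is absent or every voxel sits at or below the floor — are
#' returned as `NA` and listed in the `missing` attribute.
#'
#' @param fa numeric 3-D array (or `RNifti` image) of FA values.
#' @param labels integer 3-D array (or image) of region labels, same shape.
#' @param region_labels integer labels to extract (default: all positive
#'   labels present in `labels`).
#' @param fa_floor strict lower FA bound for inclusion (default 0.25).
#' @return named numeric vector of region means (names = label values),
#'   with attribute `missing` listing flagged labels.
#' @export
region_mean_fa <- function(fa, labels, region_labels = NULL, fa_floor = 0.25) {
  fa <- as.array(fa); labels <- as.array(labels)
  if (!identical(dim(fa), dim(labels))) stop("FA and label volume shapes differ")
  if (is.null(region_labels)) {
    region_labels <- sort(setdiff(unique(as.integer(labels)), 0L))
  }
  out <- stats::setNames(rep(NA_real_, length(region_labels)),
                         as.character(region_labels))
  for (r in region_labels) {
    v <- fa[labels == r & fa > fa_floor]
    if (length(v) > 0) out[as.character(r)] <- mean(v)
  }
  attr(out, "missing") <- region_labels[is.na(out)]
  out
}

#' Assemble a subjects x features FA table
#'
#' Binds per-subject region-mean maps into the modelling table, names the
#' region columns from the atlas list, and appends covariates. The
#' age-by-education interaction, when both covariates are present, is the
#' product of the centered variables. Missing region means (empty masks)
#' are kept as `NA` cells and reported; downstream modelling excludes such
#' columns listwise.
#'
#' @param region_maps list (one element per subject) of named vectors from
#'   [region_mean_fa()]; all subjects must share the same label set.
#' @param region_names character vector mapping label order to region
#'   names (default [mori_regions()]).
#' @param covariates optional data.frame of per-subject covariates
#'   (row-aligned with `region_maps`).
#' @return a `data.frame` (class `"minfa_cohort"`) of region means plus
#'   covariates; flagged cells reported via a message.
#' @export
build_feature_table <- function(region_maps, region_names = mori_regions(),
                                covariates = NULL) {
  labsets <- lapply(region_maps, names)
  if (length(unique(vapply(labsets, paste, "", collapse = ","))) != 1) {
    stop("inconsistent region sets across subjects")
  }
  mat <- do.call(rbind, region_maps)
  idx <- as.integer(colnames(mat))
  colnames(mat) <- unname(region_names[as.character(idx)])
  n_flagged <- sum(is.na(mat))
  if (n_flagged > 0) {
    message(sprintf("%d region cell(s) flagged missing (empty FA mask)", n_flagged))
  }
  out <- as.data.frame(mat, check.names = FALSE)
  if (!is.null(covariates)) {
    out <- cbind(out, covariates)
    if (all(c("age", "education") %in% names(out))) {
      inter <- (out$age - mean(out$age)) * (out$education - mean(out$education))
      if (all(inter == 0)) message("age:education interaction is all zero (constant input)")
      out[["age:education"]] <- inter
    }
  }
  class(out) <- c("minfa_cohort", "data.frame")
  out
}

#' Write / read a volume as NIfTI-1
#'
#' Thin wrappers over RNifti for the pre-aligned FA and label volumes.
#'
#' @param vol numeric or integer 3-D array.
#' @param path `.nii` or `.nii.gz` file path.
#' @return `write_nifti_volume`: `path` invisibly; `read_nifti_volume`:
#'   the volume as a plain array.
#' @export
write_nifti_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  as.array(RNifti::readNifti(path))
}
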