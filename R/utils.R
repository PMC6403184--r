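# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every fold contains
#' (as nearly as possible) the same class proportions. Used by the sevenfold
#' classifier averaging, the inner selection folds and the outer repeated CV.
#'
#' @param y factor-like class labels.
#' @param k number of folds; reduced with a warning if a class has fewer
#'   than `k` members.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  min_class <- min(table(y))
  if (min_class < k) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)", k, min_class))
    k <- max(2L, min_class)
  }
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Clip a value into [-1, 1]; used by the feedback display mapping.
clip1 <- function(x) pmin(1, pmax(-1, x))

# Derive a reproducible child seed (< 2^31) from a master seed and a stream id.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629 + 1
}
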