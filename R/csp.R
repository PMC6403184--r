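#' Fit common spatial patterns for a left-vs-right contrast
#'
#' Estimates spatial filters that maximize the variance of one class while
#' minimizing the variance of the other. Per-epoch covariance matrices are
#' normalized by their trace before averaging within class, then the
#' generalized eigenproblem
#' \deqn{\Sigma_{left} w = \lambda (\Sigma_{left} + \Sigma_{right}) w}
#' is solved via whitening of the pooled covariance. Eigenvalues lie in
#' \[0, 1\] and give the fraction of (normalized) variance the component
#' captures for the left class; components are returned sorted by
#' decreasing eigenvalue. A small ridge (`1e-9 * trace`) stabilizes the
#' pooled covariance on short sessions.
#'
#' @param left,right [epoch_set()]s of band-pass-filtered epochs for the
#'   two classes, same channel count and sampling rate.
#' @return an object of class `"minfa_csp"` with elements `filters`
#'   (components x channels, rows are w), `patterns` (channels x
#'   components, the inverse-transpose columns), `eigenvalues`, and
#'   `class_order = c("left", "right")`.
#' @export
fit_csp <- function(left, right) {
  if (n_epochs(left) == 0 || n_epochs(right) == 0) stop("empty epoch set")
  if (dim(left$data)[2] != dim(right$data)[2]) stop("channel mismatch")
  cov_l <- class_covariance(left)
  cov_r <- class_covariance(right)
  pooled <- cov_l + cov_r
  pooled <- pooled + diag(1e-9 * sum(diag(pooled)), nrow(pooled))
  eg <- eigen(pooled, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    stop("rank-deficient pooled covariance; reduce channels before CSP")
  }
  # whiten, diagonalize the left covariance in whitened space
  wh <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  m <- wh %*% cov_l %*% wh
  m <- (m + t(m)) / 2
  eg2 <- eigen(m, symmetric = TRUE)
  filters <- t(wh %*% eg2$vectors)        # components x channels
  lambda <- pmin(pmax(eg2$values, 0), 1)  # already sorted descending
  # sign convention: largest-magnitude pattern weight positive
  patterns <- solve(filters)              # channels x components
  for (k in seq_len(nrow(filters))) {
    j <- which.max(abs(patterns[, k]))
    if (patterns[j, k] < 0) {
      patterns[, k] <- -patterns[, k]
      filters[k, ] <- -filters[k, ]
    }
  }
  structure(
    list(filters = filters, patterns = patterns, eigenvalues = lambda,
         class_order = c("left", "right")),
    class = "minfa_csp")
}

# Average trace-normalized per-epoch covariance for one class.
class_covariance <- function(ep) {
  n_ch <- dim(ep$data)[2]
  acc <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_epochs(ep))) {
    x <- ep$data[i, , ]
    cc <- tcrossprod(x - rowMeans(x))
    acc <- acc + cc / sum(diag(cc))
  }
  acc / n_epochs(ep)
}

#' @export
print.minfa_csp <- function(x, ...) {
  cat(sprintf("<minfa_csp> %d components over %d channels; lambda range [%.3f, %.3f]\n",
              nrow(x$filters), ncol(x$filters),
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Select one filter per side
#'
#' For each side the candidate set is the three components with the most
#' extreme eigenvalue for that side (largest lambda for left, smallest for
#' right, i.e. highest variance segregation). Among the candidates the
#' selected filter maximizes a plausibility criterion; the default
#' criterion is the largest absolute pattern weight over a configured set
#' of motor-strip channels, standing in for the visual plausibility check
#' of the original protocol. Without a channel map the component with the
#' most extreme eigenvalue is taken.
#'
#' @param model a `"minfa_csp"` from [fit_csp()].
#' @param motor_channels optional integer indices of motor-strip channels
#'   used by the default plausibility criterion; `NULL` selects by extreme
#'   eigenvalue alone.
#' @param n_candidates candidates per side (default 3); if fewer
#'   components exist, all are used with a warning.
#' @return list with `left` and `right` filter row indices into
#'   `model$filters`.
#' @export
select_filters <- function(model, motor_channels = NULL, n_candidates = 3) {
  n_comp <- nrow(model$filters)
  if (n_comp < 2 * n_candidates) {
    warning("fewer components than candidate slots; using all components")
    n_candidates <- max(1L, floor(n_comp / 2))
  }
  cand_left <- seq_len(n_candidates)                    # largest lambda
  cand_right <- seq(n_comp, n_comp - n_candidates + 1)  # smallest lambda
  pick <- function(cands) {
    if (is.null(motor_channels)) return(cands[1])
    score <- apply(abs(model$patterns[motor_channels, cands, drop = FALSE]),
                   2, max)
    cands[which.max(score)]
  }
  list(left = pick(cand_left), right = pick(cand_right))
}

#' Apply spatial filters
#'
#' Projects a recording or epoch set onto the selected spatial filters,
#' yielding one virtual channel per filter (`w' x`).
#'
#' @param x a [recording()] or [epoch_set()].
#' @param filters numeric matrix, filters x channels (rows of
#'   `model$filters`), or a single filter vector.
#' @return object of the same class with the virtual channels in place of
#'   the original channels.
#' @export
apply_csp <- function(x, filters) {
  filters <- rbind(filters)
  if (inherits(x, "minfa_recording")) {
    if (ncol(filters) != nrow(x$signal)) stop("filter/channel dimension mismatch")
    return(recording(filters %*% x$signal, x$fs,
                     sprintf("csp%02d", seq_len(nrow(filters))), x$events))
  }
  if (inherits(x, "minfa_epochs")) {
    if (ncol(filters) != dim(x$data)[2]) stop("filter/channel dimension mismatch")
    out <- array(0, dim = c(dim(x$data)[1], nrow(filters), dim(x$data)[3]))
    for (i in seq_len(dim(x$data)[1])) {
      out[i, , ] <- filters %*% x$data[i, , ]
    }
    return(epoch_set(out, x$labels, x$window, x$fs))
  }
  stop("x must be a minfa_recording or minfa_epochs")
}
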