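#' Overlapping log band-power bins
#'
#' Subdivides every epoch into overlapping bins (default 1-s length,
#' 62.5-ms shift, so a 4-s epoch yields exactly 49 bins) and computes, per
#' bin and virtual channel, the logarithm of the mean squared sample value
#' (log average band power; the input is assumed CSP- and band-pass
#' filtered). Bin windows are half-open. A bin with zero power is floored
#' at `log(1e-20)` with a warning rather than producing `-Inf`.
#'
#' @param ep an [epoch_set()] (typically 2 virtual CSP channels).
#' @param bin_len bin length in seconds (default 1).
#' @param shift bin shift in seconds (default 0.0625).
#' @return object of class `"minfa_bins"`: `features` array trials x bins
#'   x channels, `labels` per trial, `bin_times` (bin start offsets in s
#'   within the epoch), `bin_len`, `shift`.
#' @export
extract_bins <- function(ep, bin_len = 1, shift = 0.0625) {
  epoch_len <- ep$window[2] - ep$window[1]
  if (epoch_len < bin_len) stop("epoch shorter than bin length")
  n_bins <- floor((epoch_len - bin_len) / shift + 1e-9) + 1
  bin_samp <- round(bin_len * ep$fs)
  shift_samp <- shift * ep$fs
  n_tr <- n_epochs(ep)
  n_ch <- dim(ep$data)[2]
  feats <- array(0, dim = c(n_tr, n_bins, n_ch))
  for (b in seq_len(n_bins)) {
    s0 <- round((b - 1) * shift_samp)
    sl <- (s0 + 1):(s0 + bin_samp)
    # mean squared amplitude per trial/channel over the bin window
    feats[, b, ] <- apply(ep$data[, , sl, drop = FALSE]^2, c(1, 2), mean)
  }
  if (any(feats <= 0)) {
    warning("zero-power bin(s) floored at log(1e-20)")
    feats[feats <= 0] <- 1e-20
  }
  structure(
    list(features = log(feats), labels = ep$labels,
         bin_times = (seq_len(n_bins) - 1) * shift,
         bin_len = bin_len, shift = shift),
    class = "minfa_bins")
}

# Flatten bin features into a (trials*bins) x channels matrix with one
# label and trial/bin index per row.
bins_as_matrix <- function(bf) {
  d <- dim(bf$features)
  x <- matrix(aperm(bf$features, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  data.frame(trial = rep(seq_len(d[1]), each = d[2]),
             bin = rep(seq_len(d[2]), d[1]),
             label = rep(bf$labels, each = d[2])) -> meta
  list(x = x, meta = meta)
}

#' Fisher linear discriminant classifier
#'
#' Two-class LDA with pooled within-class covariance and equal priors:
#' `w = S_pooled^-1 (m2 - m1)`, bias placing the boundary halfway between
#' the projected class means. Positive decision values indicate the second
#' class. A ridge is added (with a warning) if the pooled covariance is
#' singular.
#'
#' @param x numeric feature matrix, samples x features.
#' @param y binary labels (factor or character); level order fixes the
#'   sign convention.
#' @param kind optional tag (`"BaseL"`, `"BaseR"`, `"LR"`).
#' @return object of class `"minfa_lda"` with `weights`, `bias`,
#'   `classes`, `kind`.
#' @export
train_lda <- function(x, y, kind = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("NA in features")
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  cls <- levels(y)
  x1 <- x[y == cls[1], , drop = FALSE]
  x2 <- x[y == cls[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  sp <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
    (nrow(x) - 2)
  w <- tryCatch(solve(sp, m2 - m1), error = function(e) {
    warning("singular pooled covariance; ridge added")
    solve(sp + diag(1e-6 * mean(diag(sp)) + 1e-12, ncol(x)), m2 - m1)
  })
  b <- -sum(w * (m1 + m2)) / 2
  structure(list(weights = w, bias = b, classes = cls, kind = kind),
            class = "minfa_lda")
}

#' Cross-validated mean classifier
#'
#' Trains one LDA per stratified fold (each on that fold's training
#' split) and averages the fold weight vectors and biases — the "mean
#' classifier" used to drive feedback. Per-fold validation accuracies are
#' attached as `fold_accuracy`.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param folds number of folds (default 7).
#' @param kind optional classifier tag.
#' @return a `"minfa_lda"` with `fold_accuracy` and `n_folds` fields.
#' @export
train_mean_classifier <- function(x, y, folds = 7, kind = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (min(table(y)) < folds) stop("need at least `folds` samples per class")
  fid <- stratified_folds(y, folds)
  ws <- NULL; bs <- numeric(0); acc <- numeric(0)
  for (f in sort(unique(fid))) {
    tr <- fid != f
    clf <- train_lda(x[tr, , drop = FALSE], y[tr], kind = kind)
    ws <- rbind(ws, clf$weights)
    bs <- c(bs, clf$bias)
    val <- classify_segments(x[!tr, , drop = FALSE], clf)
    acc <- c(acc, mean(val$decision == as.character(y[!tr])))
  }
  out <- structure(
    list(weights = colMeans(ws), bias = mean(bs), classes = levels(y),
         kind = kind, fold_accuracy = acc, n_folds = length(bs)),
    class = "minfa_lda")
  out
}

#' Classify feature segments
#'
#' Applies a linear classifier to each row (segment/bin) of a feature
#' matrix, returning the decision and the decision-value magnitude. A
#' decision value of exactly zero is broken to the first class.
#'
#' @param x feature matrix (segments x features) or a `"minfa_bins"`
#'   object (flattened internally).
#' @param clf a `"minfa_lda"`.
#' @return data.frame with columns `decision`, `value` (and `trial`,
#'   `bin`, `label` when `x` is a `"minfa_bins"`).
#' @export
classify_segments <- function(x, clf) {
  meta <- NULL
  if (inherits(x, "minfa_bins")) {
    fl <- bins_as_matrix(x)
    meta <- fl$meta
    x <- fl$x
  }
  x <- rbind(x)
  if (ncol(x) != length(clf$weights)) stop("feature dimension mismatch")
  v <- drop(x %*% clf$weights) + clf$bias
  dec <- ifelse(v > 0, clf$classes[2], clf$classes[1])
  out <- data.frame(decision = dec, value = v)
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

#' Feedback ball position
#'
#' Maps classifier output magnitudes to the 2-D feedback display: the LR
#' decision value drives the horizontal position, the Base(L|R) value of
#' the trial's side drives the vertical position, each divided by `scale`
#' and clipped to \[-1, 1\].
#'
#' @param lr_value LR classifier decision value.
#' @param base_value BaseL or BaseR decision value for the trial side.
#' @param scale positive scaling constant mapping decision values to
#'   screen units.
#' @return numeric `c(x, y)` in \[-1, 1\]^2.
#' @export
ball_position <- function(lr_value, base_value, scale = 1) {
  if (!is.finite(lr_value) || !is.finite(base_value)) stop("non-finite input")
  if (scale <= 0) stop("scale must be positive")
  c(x = clip1(lr_value / scale), y = clip1(base_value / scale))
}
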