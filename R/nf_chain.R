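#' Score a calibration + feedback session pair
#'
#' The full neurofeedback signal chain: band-pass filtering, epoching,
#' CSP estimation on the calibration block, filter selection, log
#' band-power binning, training of the three mean classifiers (BaseL,
#' BaseR, LR) with sevenfold cross-validation, classification of the
#' feedback block's segments, and evaluation of the three performance
#' equations.
#'
#' @param calib calibration-block [recording()] (no feedback shown).
#' @param feedback feedback-block [recording()] to be scored.
#' @param band band-pass edges in Hz (default `c(8, 30)`).
#' @param mi_window MI epoch window in s relative to MI onset (default
#'   `c(0.5, 4.5)`).
#' @param baseline_window baseline epoch window (default `c(-7, -3)`).
#' @param motor_channels optional channel indices for the CSP
#'   plausibility criterion.
#' @param folds classifier-averaging folds (default 7).
#' @return a `"minfa_performance"` with the CSP model, classifiers and
#'   decision tables attached as attributes.
#' @export
nf_session_performance <- function(calib, feedback, band = c(8, 30),
                                   mi_window = c(0.5, 4.5),
                                   baseline_window = c(-7, -3),
                                   motor_channels = NULL, folds = 7) {
  calib_f <- butter_bandpass(calib, band[1], band[2])
  feed_f <- butter_bandpass(feedback, band[1], band[2])

  ep_l <- epoch(calib_f, mi_window, "left")
  ep_r <- epoch(calib_f, mi_window, "right")
  csp <- fit_csp(ep_l, ep_r)
  sel <- select_filters(csp, motor_channels = motor_channels)
  filt <- csp$filters[c(sel$left, sel$right), , drop = FALSE]

  train_bins <- function(rec, window, classes, label_as = NULL) {
    extract_bins(apply_csp(epoch(rec, window, classes, label_as), filt))
  }
  calib_sets <- list(
    left = train_bins(calib_f, mi_window, "left"),
    right = train_bins(calib_f, mi_window, "right"),
    base_l = train_bins(calib_f, baseline_window, "left", "baseline"),
    base_r = train_bins(calib_f, baseline_window, "right", "baseline"))

  make_xy <- function(a, b) {
    fa <- bins_as_matrix(a); fb <- bins_as_matrix(b)
    list(x = rbind(fa$x, fb$x), y = c(fa$meta$label, fb$meta$label))
  }
  tr_bl <- make_xy(calib_sets$base_l, calib_sets$left)
  tr_br <- make_xy(calib_sets$base_r, calib_sets$right)
  tr_lr <- make_xy(calib_sets$left, calib_sets$right)
  clf_bl <- train_mean_classifier(tr_bl$x, tr_bl$y, folds = folds, kind = "BaseL")
  clf_br <- train_mean_classifier(tr_br$x, tr_br$y, folds = folds, kind = "BaseR")
  clf_lr <- train_mean_classifier(tr_lr$x, tr_lr$y, folds = folds, kind = "LR")

  feed_sets <- list(
    left = train_bins(feed_f, mi_window, "left"),
    right = train_bins(feed_f, mi_window, "right"),
    base_l = train_bins(feed_f, baseline_window, "left", "baseline"),
    base_r = train_bins(feed_f, baseline_window, "right", "baseline"))
  dec_of <- function(a, b, clf) {
    m <- make_xy(a, b)
    cbind(classify_segments(m$x, clf), label = m$y)
  }
  dec_bl <- dec_of(feed_sets$base_l, feed_sets$left, clf_bl)
  dec_br <- dec_of(feed_sets$base_r, feed_sets$right, clf_br)
  dec_lr <- dec_of(feed_sets$left, feed_sets$right, clf_lr)

  perf <- tally_performance(dec_bl, dec_br, dec_lr)
  attr(perf, "csp") <- csp
  attr(perf, "classifiers") <- list(BaseL = clf_bl, BaseR = clf_br, LR = clf_lr)
  attr(perf, "decisions") <- list(BaseL = dec_bl, BaseR = dec_br, LR = dec_lr)
  perf
}

#' Simulate and score one synthetic subject
#'
#' Generates a calibration and a feedback block from the same
#' configuration (feedback block under a derived seed) and scores them
#' with [nf_session_performance()].
#'
#' @param cfg an [eeg_sim_config()].
#' @param ... passed to [nf_session_performance()].
#' @return a `"minfa_performance"`.
#' @export
simulate_nf_subject <- function(cfg, ...) {
  calib <- generate_eeg_session(cfg)
  cfg2 <- cfg
  cfg2$seed <- child_seed(cfg$seed, 4242)
  feedback <- generate_eeg_session(cfg2)
  nf_session_performance(calib, feedback, ...)
}

#' Write segment decisions to CSV
#' @param decisions list of decision tables (as attached to the result of
#'   [nf_session_performance()]).
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_decisions_csv <- function(decisions, path) {
  rows <- lapply(names(decisions), function(k) {
    cbind(classifier = k, decisions[[k]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
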