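#' FIR band-pass filter (Hamming window, zero phase)
#'
#' Applies a linear-phase Hamming-window FIR band-pass per channel, run
#' forward and backward so the net filter is zero-phase. The pass band
#' excludes DC, so constant offsets are removed. This is the filter used in
#' the online calibration path (8-30 Hz) and, with a 1-40 Hz band, in the
#' offline cleaning path.
#'
#' @param rec a [recording()].
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order FIR order (number of taps minus one). The default scales
#'   with the lower band edge so the transition band stays proportionally
#'   narrow: `order = ceiling(3 * fs / lo)`, rounded up to even.
#' @return a filtered [recording()] with the same events.
#' @export
fir_bandpass <- function(rec, lo, hi, order = NULL) {
  check_band(lo, hi, rec$fs)
  if (is.null(order)) order <- ceiling(3 * rec$fs / lo)
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, c(lo, hi) / (rec$fs / 2), type = "pass",
                    window = signal::hamming(order + 1))
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(x) {
    signal::filtfilt(signal::Ma(h), x - mean(x))
  }))
  out
}

#' Butterworth band-pass filter
#'
#' Fourth-order (prototype) Butterworth band-pass. The online feedback path
#' filters causally (forward only, as a real-time system must); offline use
#' applies it forward-backward for zero phase. Maximally flat design: the
#' pass-band deviation from unity gain stays below 0.5 dB away from the
#' band edges.
#'
#' @param rec a [recording()].
#' @param lo,hi band edges in Hz.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase if `TRUE` (default), filter forward-backward; if
#'   `FALSE`, causal forward pass as in the online system.
#' @return a filtered [recording()].
#' @export
butter_bandpass <- function(rec, lo, hi, order = 4, zero_phase = TRUE) {
  check_band(lo, hi, rec$fs)
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(x) {
    if (zero_phase) signal::filtfilt(bf, x) else signal::filter(bf, x)
  }))
  out
}

check_band <- function(lo, hi, fs) {
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop(sprintf("invalid band edges: need 0 < %g < %g < fs/2 = %g",
                 lo, hi, fs / 2))
  }
}

#' Flag channels with outlying temporal variance
#'
#' A channel is flagged when its temporal variance exceeds the mean
#' temporal variance by more than three standard deviations, both computed
#' across channels. The caller decides what to do with the flags (the
#' original protocol confirmed them visually before removal); the default
#' downstream policy in this package is to drop flagged channels.
#'
#' @param rec a [recording()].
#' @param n_sd flag threshold in channel-variance standard deviations
#'   (default 3).
#' @return integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_channels <- function(rec, n_sd = 3) {
  if (nrow(rec$signal) < 3) stop("need at least 3 channels")
  v <- apply(rec$signal, 1, stats::var)
  thr <- mean(v) + n_sd * stats::sd(v)
  which(v > thr)
}

#' Drop channels from a recording
#' @param rec a [recording()].
#' @param channels integer indices to remove.
#' @return a [recording()] without those channels.
#' @export
drop_channels <- function(rec, channels) {
  if (length(channels) == 0) return(rec)
  keep <- setdiff(seq_len(nrow(rec$signal)), channels)
  recording(rec$signal[keep, , drop = FALSE], rec$fs,
            rec$channel_labels[keep], rec$events)
}

#' Cut epochs around motor-imagery events
#'
#' Cuts one epoch per matching event at `window` (seconds relative to MI
#' onset, half-open `[start, end)`). Baseline epochs are obtained by
#' passing the baseline window (conventionally `c(-7, -3)`) together with
#' `label_as = "baseline"`. Events whose window would cross a recording
#' edge are skipped with a warning.
#'
#' @param rec a [recording()] with events.
#' @param window numeric length-2 window in seconds relative to MI onset.
#' @param classes which event classes to epoch (default both hands).
#' @param label_as optional label override (e.g. `"baseline"`); by default
#'   epochs inherit their event's class.
#' @return an [epoch_set()].
#' @export
epoch <- function(rec, window, classes = c("left", "right"),
                  label_as = NULL) {
  if (window[2] <= window[1]) stop("empty epoch window")
  ev <- rec$events[rec$events$class %in% classes, , drop = FALSE]
  if (nrow(ev) == 0) stop("no matching events")
  n_samp <- round((window[2] - window[1]) * rec$fs)
  start <- ev$sample + round(window[1] * rec$fs)  # 0-based
  ok <- start >= 0 & (start + n_samp) <= ncol(rec$signal)
  if (!all(ok)) {
    warning(sprintf("%d event(s) too close to recording edge; skipped",
                    sum(!ok)))
  }
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  if (nrow(ev) == 0) stop("all epochs fall outside the recording")
  dat <- array(0, dim = c(nrow(ev), nrow(rec$signal), n_samp))
  for (i in seq_len(nrow(ev))) {
    dat[i, , ] <- rec$signal[, (start[i] + 1):(start[i] + n_samp)]
  }
  labels <- if (is.null(label_as)) ev$class else rep(label_as, nrow(ev))
  epoch_set(dat, labels, window, rec$fs)
}

#' Reject epochs by amplitude threshold
#'
#' Removes every epoch containing any sample whose absolute value exceeds
#' `limit_uv` microvolts. Survivor order is preserved; an empty result is
#' returned as an empty epoch set, not an error.
#'
#' @param ep an [epoch_set()].
#' @param limit_uv rejection threshold in microvolts (default 500).
#' @return the surviving [epoch_set()].
#' @export
reject_threshold <- function(ep, limit_uv = 500) {
  if (limit_uv <= 0) stop("limit_uv must be positive")
  peak <- apply(abs(ep$data), 1, max)
  subset_epochs(ep, which(peak <= limit_uv))
}

#' Reject epochs by joint probability
#'
#' For each channel the empirical value distribution across all epochs is
#' estimated with a fixed 100-bin histogram (Laplace-smoothed so no bin has
#' zero mass). Each epoch's per-channel statistic is the joint log
#' probability of its samples (sum of log bin densities). An epoch is
#' rejected when any single channel's statistic deviates from the
#' across-epoch mean by more than `local_sd` standard deviations, or when
#' the aggregate over all channels deviates by more than `global_sd`
#' standard deviations. Decisions are made in a single pass against the
#' full-set statistics.
#'
#' @param ep an [epoch_set()] with at least 5 epochs.
#' @param local_sd per-channel threshold in SDs (default 6).
#' @param global_sd all-channel threshold in SDs (default 2).
#' @param n_bins histogram bins (default 100).
#' @return the surviving [epoch_set()].
#' @export
reject_jointprob <- function(ep, local_sd = 6, global_sd = 2, n_bins = 100) {
  n_ep <- n_epochs(ep)
  if (n_ep < 5) stop("need at least 5 epochs for joint-probability rejection")
  n_ch <- dim(ep$data)[2]
  jp <- matrix(0, n_ep, n_ch)  # epoch x channel joint log-probability
  for (ch in seq_len(n_ch)) {
    x <- ep$data[, ch, ]
    rng <- range(x)
    if (rng[1] == rng[2]) next  # constant channel carries no information
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1), n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    dens <- (counts + 1) / (sum(counts) + n_bins)  # Laplace smoothing
    logd <- log(dens)
    jp[, ch] <- rowSums(matrix(logd[bin], nrow = n_ep))
  }
  local_dev <- abs(scale(jp))           # per-channel z of the statistic
  glob <- rowSums(jp)
  glob_dev <- abs(glob - mean(glob)) / stats::sd(glob)
  bad <- apply(local_dev, 1, function(z) any(z > local_sd, na.rm = TRUE)) |
    (is.finite(glob_dev) & glob_dev > global_sd)
  subset_epochs(ep, which(!bad))
}
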