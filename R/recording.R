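#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG signal with event markers.
#' This is the unit every preprocessing step consumes and returns: a
#' channels x samples matrix in microvolts, a sampling rate, channel labels,
#' and a table of motor-imagery events (sample index of MI onset plus class).
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param events data.frame with columns `sample` (0-based index of MI onset)
#'   and `class` (`"left"` or `"right"`).
#' @return an object of class `"minfa_recording"`.
#' @export
recording <- function(signal, fs, channel_labels = NULL, events = NULL) {
  signal <- as.matrix(signal)
  if (anyNA(signal)) stop("signal contains NA values")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length must match channel count")
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), class = character(0))
  }
  if (nrow(events) > 0) {
    if (!all(events$class %in% c("left", "right"))) {
      stop("event classes must be 'left' or 'right'")
    }
    if (any(events$sample < 0) || any(events$sample >= ncol(signal))) {
      stop("event sample indices outside signal length")
    }
  }
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         events = events),
    class = "minfa_recording")
}

#' @export
print.minfa_recording <- function(x, ...) {
  cat(sprintf("<minfa_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

#' Set of equally sized epochs
#'
#' Trials x channels x samples array with per-trial class labels and the
#' epoch window in seconds relative to motor-imagery onset. Windows are
#' half-open `[start, end)` so a 4-s window at 500 Hz holds exactly 2000
#' samples.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels per-trial class, each in `c("left", "right", "baseline")`.
#' @param window numeric length-2, `(start_s, end_s)` relative to MI onset.
#' @param fs sampling rate in Hz.
#' @return an object of class `"minfa_epochs"`.
#' @export
epoch_set <- function(data, labels, window, fs) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(labels)) stop("one label per trial required")
  if (!all(labels %in% c("left", "right", "baseline"))) {
    stop("labels must be left/right/baseline")
  }
  n_samp <- round((window[2] - window[1]) * fs)
  if (abs(n_samp - dim(data)[3]) > 1) {
    stop("window length inconsistent with sample count")
  }
  structure(
    list(data = data, labels = labels, window = window, fs = fs),
    class = "minfa_epochs")
}

#' @export
print.minfa_epochs <- function(x, ...) {
  cat(sprintf("<minfa_epochs> %d trials x %d channels x %d samples, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2]))
  print(table(x$labels))
  invisible(x)
}

# Subset an epoch set by trial index, preserving metadata.
subset_epochs <- function(ep, idx) {
  epoch_set(ep$data[idx, , , drop = FALSE], ep$labels[idx], ep$window, ep$fs)
}

#' Number of trials in an epoch set
#' @param ep an `epoch_set()`.
#' @return integer trial count.
#' @export
n_epochs <- function(ep) dim(ep$data)[1]
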