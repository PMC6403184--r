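#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Describes one simulated neurofeedback block: paradigm timing, source
#' model and noise level. Defaults mirror the paradigm the pipeline
#' expects: 20 trials per hand, 500 Hz sampling, trials made of a 5-s
#' baseline, a 3-s cue and a 5-s motor-imagery period (so the trial spans
#' -8..+5 s around MI onset), separated by a 0-4 s quasi-random interval.
#'
#' @param n_channels number of scalp channels (default 16; the source
#'   model does not need a dense montage).
#' @param fs sampling rate in Hz (default 500); must exceed 60 Hz so the
#'   8-30 Hz band is well below Nyquist.
#' @param n_trials_per_class trials per hand (default 20).
#' @param trial_layout named numeric: `baseline_start`, `cue`, `mi_onset`
#'   (all in s relative to MI onset) and `mi_duration` (s). Defaults
#'   `c(-8, -3, 0, 5)`.
#' @param mu_freq sensorimotor rhythm frequency in Hz (default 11).
#' @param erd_depth fraction in `[0, 1)` by which the contralateral
#'   source amplitude drops during motor imagery (default 0.5).
#' @param snr linear source-to-noise amplitude ratio at the source's best
#'   channel (default 2).
#' @param inter_trial_jitter length-2 range in s of the quasi-random
#'   inter-trial interval (default `c(0, 4)`).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   sessions.
#' @return an `"eeg_sim_config"` list.
#' @export
eeg_sim_config <- function(n_channels = 16, fs = 500, n_trials_per_class = 20,
                           trial_layout = c(baseline_start = -8, cue = -3,
                                            mi_onset = 0, mi_duration = 5),
                           mu_freq = 11, erd_depth = 0.5, snr = 2,
                           inter_trial_jitter = c(0, 4), seed = 1) {
  if (erd_depth < 0 || erd_depth >= 1) stop("erd_depth must be in [0, 1)")
  if (fs <= 2 * 30) stop("fs must exceed 60 Hz")
  tl <- trial_layout
  if (!(tl[1] < tl[2] && tl[2] <= tl[3] && tl[4] > 0)) {
    stop("trial windows must be ordered and non-overlapping")
  }
  structure(list(n_channels = n_channels, fs = fs,
                 n_trials_per_class = n_trials_per_class,
                 trial_layout = tl, mu_freq = mu_freq, erd_depth = erd_depth,
                 snr = snr, inter_trial_jitter = inter_trial_jitter,
                 seed = seed),
            class = "eeg_sim_config")
}

#' Generate one synthetic motor-imagery EEG block
#'
#' Source model: two sinusoidal mu-rhythm sources with slow multiplicative
#' amplitude noise, one per hemisphere, mixed to the channels through
#' fixed "C3/C4-like" Gaussian spatial profiles. During motor imagery the
#' source contralateral to the imagined hand is attenuated by
#' `1 - erd_depth` (event-related desynchronization). Channel noise is
#' spectrally 1/f and channel-independent, scaled so the source-to-noise
#' amplitude ratio at each source's best channel equals `snr`.
#'
#' The returned [recording()] carries the pre-mixing source signals in
#' `attr(, "sources")` (2 x samples) and the per-trial MI windows in
#' `attr(, "mi_windows")`, so tests can verify the injected effect before
#' mixing.
#'
#' @param cfg an [eeg_sim_config()].
#' @return a [recording()] with one event per trial at MI onset.
#' @export
generate_eeg_session <- function(cfg) {
  stopifnot(inherits(cfg, "eeg_sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  tl <- cfg$trial_layout
  n_tr <- 2 * cfg$n_trials_per_class
  classes <- sample(rep(c("left", "right"), cfg$n_trials_per_class))
  trial_len <- tl[4] - tl[1]                       # baseline start to MI end
  gaps <- stats::runif(n_tr, cfg$inter_trial_jitter[1], cfg$inter_trial_jitter[2])
  pad <- 1                                          # s of lead-in/out
  onsets_s <- numeric(n_tr)                         # MI onset times
  t_cursor <- pad
  for (i in seq_len(n_tr)) {
    onsets_s[i] <- t_cursor - tl[1]                 # tl[1] negative
    t_cursor <- t_cursor + trial_len + gaps[i]
  }
  total_s <- t_cursor + pad
  n_samp <- ceiling(total_s * fs)
  tt <- (seq_len(n_samp) - 1) / fs

  # ERD gain per source: source 1 = left hemisphere (suppressed during
  # RIGHT-hand MI), source 2 = right hemisphere (suppressed during left MI)
  gain <- matrix(1, 2, n_samp)
  mi_windows <- cbind(start = round(onsets_s * fs),
                      end = round((onsets_s + tl[4]) * fs))
  for (i in seq_len(n_tr)) {
    idx <- (mi_windows[i, 1] + 1):mi_windows[i, 2]
    src <- if (classes[i] == "right") 1 else 2
    gain[src, idx] <- 1 - cfg$erd_depth
  }

  base_amp <- 10  # microvolts at the source's best channel
  sources <- matrix(0, 2, n_samp)
  # the two hemispheric rhythms get slightly different carrier frequencies
  # and independent slow phase noise so they are mutually incoherent (two
  # sources at an identical frequency would interfere rather than add in
  # power, which no real pair of mu generators does)
  freq_offset <- c(-0.35, 0.35)
  for (s in 1:2) {
    phase0 <- stats::runif(1, 0, 2 * pi)
    phase_drift <- (pi / 2) * smooth_noise(n_samp, fs, cutoff = 0.2)
    env <- 1 + 0.3 * smooth_noise(n_samp, fs, cutoff = 1)
    env <- pmax(env, 0.1)
    sources[s, ] <- base_amp * gain[s, ] * env *
      sin(2 * pi * (cfg$mu_freq + freq_offset[s]) * tt + phase0 + phase_drift)
  }

  mix <- mixing_matrix(cfg$n_channels)
  signal <- mix %*% sources
  noise_rms <- base_amp / sqrt(2) / cfg$snr
  for (ch in seq_len(cfg$n_channels)) {
    signal[ch, ] <- signal[ch, ] + noise_rms * pink_noise(n_samp)
  }

  rec <- recording(signal, fs,
                   events = data.frame(sample = mi_windows[, 1],
                                       class = classes))
  attr(rec, "sources") <- sources
  attr(rec, "mi_windows") <- mi_windows
  attr(rec, "mixing") <- mix
  attr(rec, "trial_classes") <- classes
  rec
}

# Fixed C3/C4-like mixing: Gaussian spatial profiles peaked at 1/3 and 2/3
# of the channel axis, unit peak gain.
mixing_matrix <- function(n_channels) {
  pos <- seq_len(n_channels)
  width <- max(1.5, n_channels / 8)
  cbind(exp(-((pos - (n_channels + 1) / 3)^2) / (2 * width^2)),
        exp(-((pos - 2 * (n_channels + 1) / 3)^2) / (2 * width^2)))
}

# Unit-RMS 1/f ("pink") noise: shape the spectrum of white noise by
# 1/sqrt(f) (symmetric in frequency index) and invert.
pink_noise <- function(n) {
  # pad to a 2/3/5-smooth length so the FFT stays O(n log n)
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::fft(stats::rnorm(m))
  k <- seq_len(m) - 1
  f <- pmin(k, m - k)             # physical frequency index, symmetric
  scale <- 1 / sqrt(pmax(f, 1))   # keep DC bin finite
  x <- Re(stats::fft(w * scale, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Slow Gaussian noise (low-pass below `cutoff` Hz), unit SD.
smooth_noise <- function(n, fs, cutoff = 1) {
  k <- max(3, round(fs / cutoff))
  x <- stats::filter(stats::rnorm(n + k), rep(1 / k, k), sides = 1)
  x <- as.numeric(x[(k + 1):(n + k)])
  x / stats::sd(x)
}
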