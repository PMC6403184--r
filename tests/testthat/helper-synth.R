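# Shared fixture builders (all programmatic; no data files).

# Single- or multi-channel recording holding given per-channel signals.
make_recording <- function(..., fs = 500, events = NULL) {
  recording(rbind(...), fs = fs, events = events)
}

# Sinusoidal test signal in microvolts.
sine_wave <- function(freq, fs = 500, dur = 4, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs + phase)
}

# Epoch set with externally supplied trial data (trials x channels x samples).
make_epochs <- function(data, labels, fs = 500, window = NULL) {
  if (is.null(window)) window <- c(0, dim(data)[3] / fs)
  epoch_set(data, labels, window, fs)
}

# Gaussian epochs: n trials x n_ch x n_samp, per-trial scale multipliers.
gaussian_epochs <- function(n, n_ch = 4, n_samp = 100, fs = 100, scale = 1) {
  scale <- rep_len(scale, n)
  dat <- array(rnorm(n * n_ch * n_samp), dim = c(n, n_ch, n_samp))
  dat <- dat * array(rep(scale, n_ch * n_samp), dim = dim(dat))
  make_epochs(dat, rep("left", n), fs = fs)
}

# Cohort table with a direct group shift: `d` on the named columns
# (bypasses the generator's median-split geometry; used where an exactly
# controlled, arbitrarily large separation is needed).
shifted_cohort <- function(n, p = 48, d = 0, shifted_cols = integer(0),
                           seed = 1) {
  set.seed(seed)
  label <- factor(rep(c("low", "high"), length.out = n),
                  levels = c("low", "high"))
  x <- matrix(rnorm(n * p), n, p)
  x[label == "high", shifted_cols] <- x[label == "high", shifted_cols] + d
  colnames(x) <- paste0("f", seq_len(p))
  out <- data.frame(x, check.names = FALSE)
  out$label <- label
  out
}
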