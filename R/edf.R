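# Minimal EDF (European Data Format) writer/reader: 16-bit integer
# encoding, one fixed-duration data record per second by default. Event
# markers are carried in an extra "MARKER" channel (0 = none, 1 = left MI
# onset, 2 = right MI onset) so a recording round-trips without EDF+
# annotation machinery. Values quantize to the per-channel physical range
# over 16 bits.

pad_field <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' @param rec a [recording()].
#' @param path output `.edf` path.
#' @param record_dur data-record duration in seconds (default 1;
#'   `record_dur * fs` must be an integer).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_dur = 1) {
  fs <- rec$fs
  spr <- record_dur * fs
  if (abs(spr - round(spr)) > 1e-9) stop("record_dur * fs must be integer")
  spr <- as.integer(round(spr))

  marker <- numeric(ncol(rec$signal))
  if (nrow(rec$events) > 0) {
    marker[rec$events$sample + 1] <- ifelse(rec$events$class == "left", 1, 2)
  }
  sig <- rbind(rec$signal, marker)
  labels <- c(rec$channel_labels, "MARKER")
  ns <- nrow(sig)

  n_rec <- floor(ncol(sig) / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  sig <- sig[, seq_len(n_rec * spr), drop = FALSE]

  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("synthetic subject", 80),
    pad_field("minfa synthetic recording", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format(record_dur), 8),
    pad_field(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- c(
    vapply(labels, pad_field, "", width = 16),
    vapply(rep("", ns), pad_field, "", width = 80),
    vapply(c(rep("uV", ns - 1), ""), pad_field, "", width = 8),
    vapply(sprintf("%.7g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.7g", pmax_), pad_field, "", width = 8),
    vapply(rep(dmin, ns), pad_field, "", width = 8),
    vapply(rep(dmax, ns), pad_field, "", width = 8),
    vapply(rep("", ns), pad_field, "", width = 80),
    vapply(rep(spr, ns), pad_field, "", width = 8),
    vapply(rep("", ns), pad_field, "", width = 32))
  sig_hdr <- paste0(fields, collapse = "")
  writeChar(sig_hdr, con, nchars = nchar(sig_hdr), eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round((sig[, cols, drop = FALSE] - pmin_) * gain + dmin)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the standard EDF header and 16-bit samples; a channel labelled
#' `MARKER` is converted back into the event table instead of being kept
#' as signal.
#'
#' @param path `.edf` path.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1) stop("heterogeneous sampling rates unsupported")
  spr <- spr[1]
  fs <- spr / record_dur

  sig <- matrix(0, ns, n_rec * spr)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr, size = 2, endian = "little")
    sig[, ((r - 1) * spr + 1):(r * spr)] <- matrix(raw, ns, spr, byrow = TRUE)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- (sig - dmin) * gain + pmin_

  mk <- which(labels == "MARKER")
  events <- data.frame(sample = integer(0), class = character(0))
  if (length(mk) == 1) {
    m <- round(sig[mk, ])
    idx <- which(m != 0)
    events <- data.frame(sample = idx - 1L,
                         class = ifelse(m[idx] == 1, "left", "right"))
    sig <- sig[-mk, , drop = FALSE]
    labels <- labels[-mk]
  }
  recording(sig, fs, labels, events)
}
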