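# Minimal EDF (European Data Format) writer/reader: ASCII header plus
# little-endian 16-bit data records with per-signal physical scaling. Covers
# the subset of the format the session layout needs (one data record holding
# the whole trial; per-signal labels, rates and physical ranges).

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a multichannel signal matrix to an EDF file
#'
#' @param path Output file.
#' @param signals Channels x samples numeric matrix.
#' @param labels Channel labels.
#' @param fs Sampling rate, Hz (shared by all signals).
#' @param phys_dim Physical dimension string (default "uV").
#' @return Invisibly, the per-channel physical ranges used (quantization
#'   step = range / 65534).
#' @export
write_edf <- function(path, signals, labels, fs, phys_dim = "uV") {
  stopifnot(is.matrix(signals), nrow(signals) == length(labels))
  ns <- nrow(signals)
  n <- ncol(signals)
  dur <- n / fs
  pmax_ <- apply(abs(signals), 1, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- pmax_ * 1.0001
  dig <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("eegkin session", 80), edf_pad("01.01.26", 8),
    edf_pad("00.00.00", 8), edf_num(256 + ns * 256, 8),
    edf_pad("", 44), edf_num(1, 8), edf_num(dur, 8), edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  fld(labels, 16)
  fld(rep("", ns), 80)
  fld(rep(phys_dim, ns), 8)
  fld(vapply(-pmax_, edf_num, character(1), width = 8), 8)
  fld(vapply(pmax_, edf_num, character(1), width = 8), 8)
  fld(rep(-dig, ns), 8)
  fld(rep(dig, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(n, ns), 8)
  fld(rep("", ns), 32)
  for (i in seq_len(ns)) {
    d <- as.integer(round(signals[i, ] / pmax_[i] * dig))
    writeBin(d, con, size = 2, endian = "little")
  }
  invisible(pmax_)
}

#' Read an EDF file written by [write_edf()] (or any single-record EDF)
#'
#' @param path EDF file.
#' @return List: `signals` (channels x samples), `labels`, `fs`, `phys_dim`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  phys_dim <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  sig <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      sig[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs <- spr[1] / dur
  list(signals = sig, labels = labels, fs = fs, phys_dim = phys_dim)
}
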