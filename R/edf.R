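# Minimal EDF (European Data Format) container support.
#
# Plain EDF: 256-byte fixed header, 256 bytes per signal, then 1-second
# data records of 16-bit little-endian integers, one block per signal per
# record. Physical scaling is per channel from the data range. This covers
# what the pipeline needs (continuous multichannel EEG plus a trigger
# channel at one rate); annotations/EDF+ discontinuities are not supported.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(sprintf("%.*g", width - 2L, x), width)

#' Write signals to an EDF file
#'
#' @param signals numeric matrix, samples x channels. Trailing samples that
#'   do not fill a whole 1 s record are zero-padded.
#' @param path output path.
#' @param sample_rate sampling rate (Hz), shared by all channels.
#' @param labels channel labels (default `colnames(signals)` or `Ch1..`).
#' @param phys_dim physical dimension string (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, sample_rate,
                      labels = NULL, phys_dim = "uV") {
  stopifnot(is.matrix(signals))
  ns <- ncol(signals)
  labels <- labels %||% colnames(signals) %||% sprintf("Ch%d", seq_len(ns))
  spr <- as.integer(round(sample_rate))
  n_rec <- as.integer(ceiling(nrow(signals) / spr))
  ntot <- n_rec * spr
  if (nrow(signals) < ntot)
    signals <- rbind(signals, matrix(0, ntot - nrow(signals), ns))
  pmin_ <- apply(signals, 2, min)
  pmax_ <- apply(signals, 2, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))                       # patient id
  wr(pad_field("Startdate X X X X", 80))             # recording id
  wr(pad_field("01.01.00", 8)); wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (ns + 1L), 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))                              # record duration (s)
  wr(pad_field(ns, 4))
  wr(pad_field(labels, 16))
  wr(pad_field(rep("", ns), 80))                     # transducer
  wr(pad_field(rep(phys_dim, ns), 8))
  wr(vapply(pmin_, num_field, "", width = 8L))
  wr(vapply(pmax_, num_field, "", width = 8L))
  wr(pad_field(rep(dmin, ns), 8))
  wr(pad_field(rep(dmax, ns), 8))
  wr(pad_field(rep("", ns), 80))                     # prefiltering
  wr(pad_field(rep(spr, ns), 8))
  wr(pad_field(rep("", ns), 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- matrix(0L, ntot, ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round((signals[, j] - pmin_[j]) * scale[j]) + dmin)
  # interleave per record: record r holds spr samples of ch1, then ch2, ...
  idx <- matrix(seq_len(ntot), spr)   # spr x n_rec
  out <- integer(ntot * ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    block <- dig[idx[, r], , drop = FALSE]
    out[pos + seq_len(spr * ns)] <- as.integer(block)
    pos <- pos + spr * ns
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF path.
#' @return list with `signals` (samples x channels matrix), `sample_rate`,
#'   `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1L)
  spr1 <- spr[1]
  raw <- readBin(con, "integer", n = n_rec * spr1 * ns, size = 2L,
                 signed = TRUE, endian = "little")
  sig <- matrix(0, n_rec * spr1, ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[pos + seq_len(spr1 * ns)], spr1, ns)
    sig[(r - 1L) * spr1 + seq_len(spr1), ] <- block
    pos <- pos + spr1 * ns
  }
  for (j in seq_len(ns))
    sig[, j] <- (sig[, j] - dmin[j]) / (dmax[j] - dmin[j]) *
      (pmax_[j] - pmin_[j]) + pmin_[j]
  colnames(sig) <- labels
  list(signals = sig, sample_rate = spr1 / rec_dur, labels = labels)
}
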