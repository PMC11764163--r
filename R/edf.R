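# Minimal European Data Format (EDF) support: 16-bit integer encoding, one
# data record holding the whole epoch (our epochs are short; the EDF record
# size is unconstrained by this reader/writer pair). Physical scaling is
# derived from the header strings actually written, so a round trip is exact
# up to the 16-bit quantisation step.

edf_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 5)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a channels-by-samples matrix as an EDF file
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one per channel.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(data, sampling_rate, channel_labels, path) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  ns <- nrow(data)
  n_samp <- ncol(data)
  dmin <- -32768; dmax <- 32767
  pmin_str <- character(ns); pmax_str <- character(ns)
  for (ch in seq_len(ns)) {
    lo <- min(data[ch, ]); hi <- max(data[ch, ])
    if (hi <= lo) hi <- lo + 1   # constant channel: avoid zero span
    span <- hi - lo
    # widen slightly before formatting so the (rounded) header strings are
    # guaranteed to bracket the data
    pmin_str[ch] <- edf_num(lo - span * 1e-3 - abs(lo) * 1e-4)
    pmax_str[ch] <- edf_num(hi + span * 1e-3 + abs(hi) * 1e-4)
  }
  # scale with the values exactly as the reader will re-parse them
  pmin <- as.numeric(pmin_str); pmax <- as.numeric(pmax_str)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(1, 8),
    edf_field(formatC(n_samp / sampling_rate, format = "g", digits = 7), 8),
    edf_field(ns, 4),
    paste(edf_field(channel_labels, 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(formatC(pmin_str, width = 8, flag = "-"), collapse = ""),
    paste(formatC(pmax_str, width = 8, flag = "-"), collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(n_samp, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((data[ch, ] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any single-record EDF)
#'
#' @param path File path.
#' @return List with `data` (channels x samples), `sampling_rate`,
#'   `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                 # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  list(data = data, sampling_rate = spr[1] / rec_dur, channel_labels = labels)
}
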