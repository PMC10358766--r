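# Minimal European Data Format (EDF) support: continuous multichannel
# signals, 16-bit little-endian samples, one common sampling rate. Covers
# what EEG epoching needs; EDF+ annotations are not parsed.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_field <- function(con, width) trimws(readChar(con, width, useBytes = TRUE))

#' Write a recording to an EDF file
#'
#' Writes a samples-by-channels matrix as a continuous EDF recording with
#' one-second data records and a per-channel symmetric physical range.
#' Samples are quantized to the 16-bit digital grid, so values round-trip
#' to within `max(abs(x)) / 32767` per channel.
#'
#' @param samples Numeric matrix, time along rows, channels along columns (uV).
#' @param fs Sampling rate in Hz; `nrow(samples)` must be a whole number of
#'   seconds at this rate.
#' @param channel_names Character vector, one label per column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(samples, fs, channel_names, path) {
  samples <- as.matrix(samples)
  ns <- ncol(samples)
  stopifnot(length(channel_names) == ns, fs > 0)
  n_rec <- nrow(samples) / fs
  if (n_rec != round(n_rec)) {
    stop_stteeg("EDF writer needs a whole number of seconds of data",
                "stteeg_format_error")
  }
  n_rec <- as.integer(round(n_rec))

  phys_max <- pmax(apply(abs(samples), 2, max), 1e-6)
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  sig <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL, useBytes = TRUE)
  }
  sig(channel_names, 16)
  sig(rep("", ns), 80)
  sig(rep("uV", ns), 8)
  sig(sprintf("%.7g", -phys_max), 8)
  sig(sprintf("%.7g", phys_max), 8)
  sig(rep(-32768L, ns), 8)
  sig(rep(dig_max, ns), 8)
  sig(rep("", ns), 80)
  sig(rep(as.integer(fs), ns), 8)
  sig(rep("", ns), 32)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round(sweep(samples[rows, , drop = FALSE], 2, scale, `*`))
    block <- pmin(pmax(block, -32768), 32767)
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path Path to an EDF file.
#' @return List with `samples` (time-by-channels matrix, physical units),
#'   `fs` (Hz), and `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                              # version
  edf_field(con, 80); edf_field(con, 80)         # patient / recording id
  edf_field(con, 8); edf_field(con, 8)           # start date / time
  edf_field(con, 8); edf_field(con, 44)          # header bytes / reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1) {
    stop_stteeg("Malformed EDF header", "stteeg_format_error")
  }
  fields <- function(width) vapply(seq_len(ns), function(i) edf_field(con, width), "")
  labels <- fields(16)
  fields(80); fields(8)                          # transducer / dimension
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)                                     # prefiltering
  spr <- as.integer(fields(8))                   # samples per record
  fields(32)                                     # reserved

  if (length(unique(spr)) != 1L) {
    stop_stteeg("EDF signals with mixed sampling rates are not supported",
                "stteeg_format_error")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     endian = "little", signed = TRUE)
      out[rows, s] <- dig * gain[s] + offset[s]
    }
  }
  list(samples = out, fs = spr[1] / rec_dur, channel_names = labels)
}
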