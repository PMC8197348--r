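# Minimal single-channel EDF (16-bit European Data Format) support for
# the EEG channel; physical dimension fixed to uV.

.edfPad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field overflow", call. = FALSE)
  formatC(s, width = width, flag = "-")
}

#' Export an EEG record to EDF
#'
#' Writes a one-channel 16-bit EDF file.  The physical range is symmetric
#' around zero at the record's peak amplitude, so the quantization step
#' is `2 * peak / 65535` uV.  Signals whose length is a whole number of
#' seconds are stored as 1-s data records; other lengths are stored as a
#' single data record.
#'
#' @param record an [EEGRecord-class].
#' @param path output file.
#' @param label channel label (up to 16 ASCII characters).
#' @return invisibly, `path`.
#' @export
writeEDF <- function(record, path, label = "EEG Fp") {
  stopifnot(is(record, "EEGRecord"))
  x <- samples(record)
  fs <- samplingRate(record)
  n <- length(x)
  if (!n) stop("empty record", call. = FALSE)
  if (n %% round(fs) == 0) {
    spr <- round(fs)                  # samples per 1-s record
    nRec <- n %/% spr
    recDur <- 1
  } else {
    if (2 * n > 61440)
      stop("record length is not a whole number of seconds and exceeds one EDF data record",
           call. = FALSE)
    spr <- n
    nRec <- 1L
    recDur <- n / fs
  }
  pm <- signif(max(max(abs(x)), 1e-3) * 1.0000001, 6)
  pmStr <- sprintf("%.6g", pm)
  pm <- as.numeric(pmStr)             # use the printed value exactly
  digMin <- -32768
  digMax <- 32767
  d <- round((x + pm) / (2 * pm) * (digMax - digMin)) + digMin
  d <- pmin(pmax(d, digMin), digMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("synthetic swine", 80),
    .edfPad("qeegcpr export", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * 2, 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad(format(recDur, digits = 6), 8),
    .edfPad(1, 4),
    # signal header block (one signal)
    .edfPad(label, 16), .edfPad("synthetic", 80), .edfPad("uV", 8),
    .edfPad(paste0("-", pmStr), 8), .edfPad(pmStr, 8),
    .edfPad(digMin, 8), .edfPad(digMax, 8),
    .edfPad("BP:0.5-47Hz", 80), .edfPad(spr, 8), .edfPad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(d), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' @param path an EDF file written by [writeEDF()] (or any one-channel
#'   16-bit EDF with a uV-scaled signal).
#' @return an [EEGRecord-class].
#' @export
readEDF <- function(path) {
  if (!file.exists(path))
    stop(sprintf("EDF file '%s' is missing", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readField <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  readField(8)                        # version
  readField(80); readField(80)        # patient, recording
  readField(8); readField(8)          # date, time
  headerBytes <- as.numeric(readField(8))
  readField(44)
  nRec <- as.numeric(readField(8))
  recDur <- as.numeric(readField(8))
  ns <- as.numeric(readField(4))
  if (ns != 1)
    stop("only single-channel EDF files are supported", call. = FALSE)
  readField(16); readField(80)        # label, transducer
  dim <- readField(8)
  physMin <- as.numeric(readField(8))
  physMax <- as.numeric(readField(8))
  digMin <- as.numeric(readField(8))
  digMax <- as.numeric(readField(8))
  readField(80)                       # prefiltering
  spr <- as.numeric(readField(8))
  readField(32)
  seek(con, headerBytes)
  d <- readBin(con, integer(), n = nRec * spr, size = 2, signed = TRUE,
               endian = "little")
  x <- physMin + (d - digMin) * (physMax - physMin) / (digMax - digMin)
  EEGRecord(x, fs = spr / recDur)
}
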