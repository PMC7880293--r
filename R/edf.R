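# Minimal EDF (European Data Format) I/O: 16-bit integer samples, one
# header of 256 + 256 * nSignals bytes, one-second data records. The final
# record is zero-padded; the true sample count and the recording start time
# (ms, event-table clock) travel in the reserved header field so that a
# write -> read round trip restores the exact recording geometry.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space-padded
}

edfNum <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(signif(x, digits), format = "g", digits = digits, width = 1)
    if (nchar(s) <= width) return(edfPad(s, width))
  }
  stopf("cannot format %g in %d characters", x, width)
}

#' Write a recording to an EDF file
#'
#' Serializes a [Recording-class] as 16-bit EDF with physical units uV.
#' Each channel's physical range is symmetric about zero and spans the
#' channel's absolute maximum, so the quantization step is
#' `2 * max(abs(v)) / 65535`; round-trip voltage error is at most half a
#' step. Events are not part of EDF and are written separately with
#' [writeEventTable()].
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecordingEdf <- function(recording, path) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@fsHz
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate (got %g)", fs)
  fs <- round(fs)
  nCh <- length(recording@channelNames)
  nSamp <- ncol(recording@data)
  nRec <- ceiling(nSamp / fs)
  # format the magnitude once, in 7 chars so "-<mag>" also fits in 8, and
  # reuse the parsed value for scaling: written and read gains agree exactly
  physMaxStr <- vapply(seq_len(nCh), function(i) {
    m <- max(abs(recording@data[i, ]), 1e-6)
    trimws(edfNum(m * 1.0001, width = 7))
  }, "")
  physMax <- as.numeric(physMaxStr)
  gains <- physMax * 2 / 65535

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edfPad("0", 8), edfPad("X X X X", 80),
    edfPad("Startdate X X X X", 80),
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(256 * (nCh + 1), 8),
    edfPad(sprintf("NSAMP=%d STARTMS=%g", nSamp, recording@startMs), 44),
    edfPad(nRec, 8), edfPad("1", 8), edfPad(nCh, 4)
  ), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(recording@channelNames, 16)
  field(rep("simulated EEG", nCh), 80)
  field(rep("uV", nCh), 8)
  field(paste0("-", physMaxStr), 8)
  field(physMaxStr, 8)
  field(rep("-32768", nCh), 8)
  field(rep("32767", nCh), 8)
  field(rep("", nCh), 80)
  field(rep(fs, nCh), 8)
  field(rep("", nCh), 32)

  padded <- matrix(0, nrow = nCh, ncol = nRec * fs)
  padded[, seq_len(nSamp)] <- recording@data
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nCh)) {
      dig <- round(padded[i, cols] / gains[i])
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording (with optional event CSV)
#'
#' Reads a 16-bit EDF file written by [writeRecordingEdf()] (or any EDF
#' whose signals share one sampling rate and have physical dimension uV)
#' and optionally attaches an event table read with [readEventTable()].
#'
#' @param path EDF file path.
#' @param eventsPath optional path of the companion event CSV; an empty
#'   event file is an error.
#' @param channels optional expected channel names; a mismatch between the
#'   EDF channel count/names and this vector is an error.
#' @return a [Recording-class].
#' @export
readRecordingEdf <- function(path, eventsPath = NULL, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(readChar(con, nchars, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  reserved <- rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  labels <- vapply(seq_len(nCh), function(i) rd(16), "")
  vapply(seq_len(nCh), function(i) rd(80), "")
  dims <- vapply(seq_len(nCh), function(i) rd(8), "")
  physMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  vapply(seq_len(nCh), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(nCh), function(i) rd(8), ""))
  vapply(seq_len(nCh), function(i) rd(32), "")

  if (any(dims != "uV"))
    stopf("unit mismatch: expected physical dimension 'uV', got %s",
          paste(unique(dims), collapse = ", "))
  if (length(unique(spr)) != 1)
    stopf("signals with differing sampling rates are not supported")
  if (!is.null(channels)) {
    if (nCh != length(channels) || !all(labels == channels))
      stopf("channel mismatch: EDF has [%s], expected [%s]",
            paste(labels, collapse = ","), paste(channels, collapse = ","))
  }
  fs <- spr[1] / recDur
  gains <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, nrow = nCh, ncol = nRec * spr[1],
                 dimnames = list(labels, NULL))
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      data[i, cols] <- physMin[i] + (dig - digMin[i]) * gains[i]
    }
  }
  nSamp <- ncol(data)
  startMs <- 0
  m <- regmatches(reserved, regexec("NSAMP=([0-9]+) STARTMS=(-?[0-9.]+)", reserved))[[1]]
  if (length(m) == 3) {
    nSamp <- as.integer(m[2])
    startMs <- as.numeric(m[3])
    data <- data[, seq_len(nSamp), drop = FALSE]
  }
  ev <- if (is.null(eventsPath)) {
    new("EventTable",
        events = data.frame(onset_ms = numeric(0), label = character(0),
                            sequence_kind = character(0), index = integer(0)),
        stimulusDurationMs = 150, isiMs = 400,
        labelRoles = c(unknown = "standard"))
  } else {
    readEventTable(eventsPath)
  }
  new("Recording", data = data, fsHz = fs, channelNames = labels,
      reference = "as recorded", startMs = startMs, events = ev)
}
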