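#' Preprocessing configuration constructor
#'
#' Defaults implement the conventional MMN preprocessing chain: resample to
#' 500 Hz, re-reference to the mastoid mean, zero-phase 1-30 Hz band-pass,
#' epoch into \[-100, 300) ms windows with 100-ms prestimulus baseline
#' correction, reject epochs exceeding +-70 uV, and exclude the first 10
#' stimuli of each sequence plus the first standard after each deviant.
#'
#' @param targetFsHz,rerefChannels,highpassHz,lowpassHz see
#'   [PreprocessConfig-class].
#' @param epochStartMs,epochEndMs,rejectThresholdUv,nInitialExcluded,filterOrder
#'   see [PreprocessConfig-class].
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(targetFsHz = 500, rerefChannels = mastoidChannels(),
                             highpassHz = 1, lowpassHz = 30,
                             epochStartMs = -100, epochEndMs = 300,
                             rejectThresholdUv = 70, nInitialExcluded = 10,
                             filterOrder = 4) {
  new("PreprocessConfig", targetFsHz = targetFsHz,
      rerefChannels = rerefChannels, highpassHz = highpassHz,
      lowpassHz = lowpassHz, epochStartMs = epochStartMs,
      epochEndMs = epochEndMs, rejectThresholdUv = rejectThresholdUv,
      nInitialExcluded = nInitialExcluded, filterOrder = filterOrder)
}

#' Resample a recording
#'
#' Anti-aliased polyphase resampling to a lower rate: zero-stuff by the
#' rational factor's numerator where needed, apply a zero-phase Butterworth
#' anti-alias low-pass (forward-backward, so the downsampled grid stays
#' exactly aligned with the original time axis — no group delay), and pick
#' every q-th sample. Event onsets are stored in milliseconds and are
#' therefore unchanged; only the sample grid moves.
#'
#' @param recording a [Recording-class].
#' @param targetFsHz new sampling rate; must not exceed the current rate.
#' @return the resampled [Recording-class].
#' @export
resampleRecording <- function(recording, targetFsHz) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@fsHz
  if (targetFsHz > fs)
    stopf("upsampling (%g -> %g Hz) is not supported", fs, targetFsHz)
  if (targetFsHz == fs) return(recording)
  g <- gcdInt(round(targetFsHz), round(fs))
  p <- round(targetFsHz) / g
  q <- round(fs) / g
  newData <- t(apply(recording@data, 1, resampleVector, p = p, q = q))
  rownames(newData) <- recording@channelNames
  recording@data <- newData
  recording@fsHz <- targetFsHz
  recording
}

resampleVector <- function(x, p, q) {
  if (p > 1) {
    up <- numeric(length(x) * p)
    up[seq(1, length(up), by = p)] <- x * p
    x <- up
  }
  bf <- signal::butter(6, 0.9 / q, type = "low")
  xf <- signal::filtfilt(bf, x)
  xf[seq(1, length(xf), by = q)]
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Re-reference a recording to a channel average
#'
#' Subtracts the instantaneous mean of the reference channels (by default
#' the two mastoids) from every channel. Because auditory MMN generators
#' invert polarity at the mastoids, mastoid re-referencing increases the
#' fronto-central MMN amplitude (improving its signal-to-noise ratio).
#'
#' @param recording a [Recording-class].
#' @param rerefChannels channels whose mean becomes the new reference; all
#'   must be present in the recording.
#' @return the re-referenced [Recording-class] with an updated reference
#'   description.
#' @export
rereferenceRecording <- function(recording, rerefChannels = mastoidChannels()) {
  stopifnot(is(recording, "Recording"))
  missing <- setdiff(rerefChannels, recording@channelNames)
  if (length(missing) > 0)
    stopf("reference channel(s) missing from the recording: %s",
          paste(missing, collapse = ", "))
  idx <- match(rerefChannels, recording@channelNames)
  ref <- colMeans(recording@data[idx, , drop = FALSE])
  recording@data <- sweep(recording@data, 2, ref, "-")
  recording@reference <- sprintf("mean(%s)", paste(rerefChannels, collapse = ","))
  recording
}

#' Zero-phase band-pass filter a recording
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift so MMN latencies are not
#' displaced. With the default 4th-order section the effective magnitude
#' response is 8th order; DC is fully removed and the 1-30 Hz passband is
#' flat to within a few percent.
#'
#' @param recording a [Recording-class].
#' @param highpassHz,lowpassHz band edges, Hz; must satisfy
#'   `0 < highpassHz < lowpassHz < fs/2`.
#' @param order Butterworth section order before the forward-backward pass.
#' @return the filtered [Recording-class].
#' @export
bandpassRecording <- function(recording, highpassHz = 1, lowpassHz = 30,
                              order = 4) {
  stopifnot(is(recording, "Recording"))
  nyq <- recording@fsHz / 2
  if (!(0 < highpassHz && highpassHz < lowpassHz && lowpassHz < nyq))
    stopf("invalid band [%g, %g] Hz for Nyquist %g Hz",
          highpassHz, lowpassHz, nyq)
  bf <- signal::butter(order, c(highpassHz, lowpassHz) / nyq, type = "pass")
  recording@data <- t(apply(recording@data, 1,
                            function(x) signal::filtfilt(bf, x)))
  rownames(recording@data) <- recording@channelNames
  recording
}

#' Cut a recording into baseline-corrected epochs
#'
#' Segments the recording into one epoch per event over the half-open
#' window `[epochStartMs, epochEndMs)` on the analysis grid (200 samples at
#' 500 Hz for the default -100 to 300 ms window), subtracting the mean of
#' the prestimulus interval `[epochStartMs, 0)` per channel and epoch.
#' Onsets are mapped to the nearest sample, ties rounding toward -Inf.
#' Events without full epoch support are not dropped: they receive status
#' `design_excluded` with reason `boundary` and a zero-filled data slice.
#'
#' @param recording a [Recording-class].
#' @param config a [PreprocessConfig-class].
#' @return an [EpochSet-class] with all statuses initialised to `kept` (or
#'   `boundary`-excluded).
#' @export
epochRecording <- function(recording, config = preprocessConfig()) {
  stopifnot(is(recording, "Recording"))
  validObject(config)
  fs <- recording@fsHz
  dt <- 1000 / fs
  times <- seq(config@epochStartMs, config@epochEndMs - dt, by = dt)
  offsets <- round(times / dt)
  ev <- recording@events@events
  roles <- recording@events@labelRoles
  nEp <- nrow(ev)
  nCh <- length(recording@channelNames)
  data <- array(0, dim = c(nEp, nCh, length(times)))
  status <- rep("kept", nEp)
  reason <- rep("", nEp)
  nSamp <- ncol(recording@data)
  baselineSel <- times < 0
  for (r in seq_len(nEp)) {
    center <- nearestSampleTiesDown((ev$onset_ms[r] - recording@startMs) / dt) + 1
    idx <- center + offsets
    if (idx[1] < 1 || idx[length(idx)] > nSamp) {
      status[r] <- "design_excluded"
      reason[r] <- "boundary"
      next
    }
    seg <- recording@data[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg[, baselineSel, drop = FALSE])
    data[r, , ] <- seg
  }
  info <- data.frame(index = ev$index, label = ev$label,
                     role = unname(roles[ev$label]),
                     sequence_kind = ev$sequence_kind,
                     status = status, reason = reason,
                     stringsAsFactors = FALSE)
  new("EpochSet", data = data, times = times, fsHz = fs,
      channelNames = recording@channelNames, info = info,
      provenance = list(
        epoch_window_ms = c(config@epochStartMs, config@epochEndMs),
        baseline_ms = c(config@epochStartMs, 0),
        reference = recording@reference))
}

#' Flag design-based epoch exclusions
#'
#' Marks as `design_excluded` (i) the first `nInitial` epochs of the
#' sequence regardless of label (reason `initial`), and (ii) every standard
#' epoch whose immediate predecessor is a deviant (reason `post_deviant`),
#' because the response to the first standard after a deviant carries
#' residual deviance-related activity. Design exclusions take precedence
#' over artifact rejection, so rejection rates refer to analyzable epochs;
#' apply this step before [rejectArtifacts()].
#'
#' @param epochs an [EpochSet-class] whose epochs are in sequence order.
#' @param nInitial number of sequence-initial epochs to exclude.
#' @return the updated [EpochSet-class].
#' @export
flagDesignExclusions <- function(epochs, nInitial = 10) {
  stopifnot(is(epochs, "EpochSet"))
  info <- epochs@info
  n <- nrow(info)
  if (n == 0) return(epochs)
  take <- seq_len(min(nInitial, n))
  info$status[take] <- "design_excluded"
  info$reason[take] <- "initial"
  if (n > 1) {
    postDev <- which(info$role[-1] == "standard" &
                     info$role[-n] == "deviant") + 1
    postDev <- setdiff(postDev, take)
    info$status[postDev] <- "design_excluded"
    info$reason[postDev] <- "post_deviant"
  }
  epochs@info <- info
  epochs
}

#' Reject artifact-laden epochs
#'
#' Sets status `artifact_rejected` (reason `amplitude`) for every currently
#' kept epoch in which any channel at any sample exceeds the threshold in
#' absolute value. The comparison is strict: an epoch peaking at exactly
#' the threshold is retained. Epochs already excluded by design keep their
#' status.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param thresholdUv rejection threshold, uV (default 70).
#' @return the updated [EpochSet-class].
#' @export
rejectArtifacts <- function(epochs, thresholdUv = 70) {
  stopifnot(is(epochs, "EpochSet"))
  info <- epochs@info
  for (r in which(info$status == "kept")) {
    if (max(abs(epochs@data[r, , ])) > thresholdUv) {
      info$status[r] <- "artifact_rejected"
      info$reason[r] <- "amplitude"
    }
  }
  epochs@info <- info
  epochs
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying the canonical stage order: resample,
#' re-reference, band-pass, epoch + baseline-correct, flag design
#' exclusions, then reject artifacts among the remaining epochs.
#'
#' @param recording a [Recording-class].
#' @param config a [PreprocessConfig-class].
#' @return an [EpochSet-class].
#' @export
preprocessRecording <- function(recording, config = preprocessConfig()) {
  recording <- resampleRecording(recording, config@targetFsHz)
  recording <- rereferenceRecording(recording, config@rerefChannels)
  recording <- bandpassRecording(recording, config@highpassHz,
                                 config@lowpassHz, config@filterOrder)
  epochs <- epochRecording(recording, config)
  epochs <- flagDesignExclusions(epochs, config@nInitialExcluded)
  epochs <- rejectArtifacts(epochs, config@rejectThresholdUv)
  epochs@provenance <- c(epochs@provenance, list(
    target_fs_hz = config@targetFsHz,
    band_hz = c(config@highpassHz, config@lowpassHz),
    filter = sprintf("zero-phase Butterworth order %d", config@filterOrder),
    reject_threshold_uv = config@rejectThresholdUv,
    n_initial_excluded = config@nInitialExcluded,
    stage_order = c("resample", "rereference", "bandpass",
                    "epoch+baseline", "design_exclusions", "artifact_rejection")))
  epochs
}
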