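#' Average kept epochs into an ERP waveform
#'
#' Pointwise mean over the kept epochs matching the selector (label and/or
#' sequence kind) on one channel. Rejected and design-excluded epochs never
#' enter the average; the number of contributing epochs is recorded.
#'
#' @param epochs an [EpochSet-class].
#' @param label syllable label to select, or `NULL` for all.
#' @param sequenceKind `"oddball"`/`"control"`, or `NULL` for all.
#' @param channel channel name (default FCz, where the MMN is maximal).
#' @param session session tag stored in the result's metadata.
#' @return a [Waveform-class].
#' @export
averageErp <- function(epochs, label = NULL, sequenceKind = NULL,
                       channel = "FCz", session = NA_character_) {
  stopifnot(is(epochs, "EpochSet"))
  if (!(channel %in% epochs@channelNames))
    stopf("channel '%s' not in the epoch set", channel)
  info <- epochs@info
  sel <- info$status == "kept"
  if (!is.null(label)) sel <- sel & info$label == label
  if (!is.null(sequenceKind)) sel <- sel & info$sequence_kind == sequenceKind
  if (!any(sel))
    stopf("no kept epochs match selector (label=%s, sequence_kind=%s)",
          if (is.null(label)) "*" else label,
          if (is.null(sequenceKind)) "*" else sequenceKind)
  ch <- match(channel, epochs@channelNames)
  vals <- colMeans(epochs@data[sel, ch, , drop = FALSE][, 1, ])
  new("Waveform", values = as.numeric(vals), times = epochs@times,
      fsHz = epochs@fsHz, channel = channel,
      label = if (is.null(label)) "all" else label,
      sequenceKind = if (is.null(sequenceKind)) "all" else sequenceKind,
      session = session, method = "average", nEpochs = sum(sel))
}

checkSameGrid <- function(a, b) {
  if (a@channel != b@channel)
    stopf("channel mismatch: %s vs %s", a@channel, b@channel)
  if (length(a@times) != length(b@times) || any(a@times != b@times))
    stopf("time-grid mismatch between waveforms")
  if (!identical(a@session, b@session) &&
      !(is.na(a@session) && is.na(b@session)))
    stopf("session mismatch: %s vs %s", a@session, b@session)
}

#' Traditional MMN difference wave
#'
#' Deviant-minus-standard subtraction within the oddball sequence: the ERP
#' evoked by the frequent standard is subtracted pointwise from the ERP
#' evoked by the infrequent deviant recorded in the same sequence. Simple,
#' but the two ERPs come from acoustically different stimuli, so exogenous
#' response differences contaminate the deviance-related negativity.
#'
#' @param deviant [Waveform-class] of the oddball deviant.
#' @param standard [Waveform-class] of the oddball standard; same channel,
#'   grid and session.
#' @return a difference [Waveform-class] with `method = "traditional"`.
#' @export
traditionalMmn <- function(deviant, standard) {
  stopifnot(is(deviant, "Waveform"), is(standard, "Waveform"))
  checkSameGrid(deviant, standard)
  new("Waveform", values = deviant@values - standard@values,
      times = deviant@times, fsHz = deviant@fsHz, channel = deviant@channel,
      label = deviant@label, sequenceKind = "difference",
      session = deviant@session, method = "traditional",
      nEpochs = min(deviant@nEpochs, standard@nEpochs))
}

#' Identity (same-stimulus) MMN difference wave
#'
#' Subtracts the ERP evoked by a syllable presented frequently in its own
#' control sequence from the ERP evoked by the physically identical
#' syllable presented infrequently in the oddball sequence. Comparing
#' acoustically identical stimuli removes the exogenous confound of the
#' traditional subtraction; both waveforms must therefore be for the same
#' label (that is the defining constraint of the method).
#'
#' @param oddballDeviant [Waveform-class] of the label as oddball deviant.
#' @param controlSameStimulus [Waveform-class] of the same label in its
#'   control sequence.
#' @return a difference [Waveform-class] with `method = "identity"`.
#' @export
identityMmn <- function(oddballDeviant, controlSameStimulus) {
  stopifnot(is(oddballDeviant, "Waveform"), is(controlSameStimulus, "Waveform"))
  if (oddballDeviant@label != controlSameStimulus@label)
    stopf(paste0("identity MMN requires the SAME stimulus in both contexts: ",
                 "got '%s' (oddball) vs '%s' (control)"),
          oddballDeviant@label, controlSameStimulus@label)
  if (oddballDeviant@channel != controlSameStimulus@channel)
    stopf("channel mismatch: %s vs %s", oddballDeviant@channel,
          controlSameStimulus@channel)
  if (length(oddballDeviant@times) != length(controlSameStimulus@times) ||
      any(oddballDeviant@times != controlSameStimulus@times))
    stopf("time-grid mismatch between waveforms")
  new("Waveform",
      values = oddballDeviant@values - controlSameStimulus@values,
      times = oddballDeviant@times, fsHz = oddballDeviant@fsHz,
      channel = oddballDeviant@channel, label = oddballDeviant@label,
      sequenceKind = "difference", session = oddballDeviant@session,
      method = "identity",
      nEpochs = min(oddballDeviant@nEpochs, controlSameStimulus@nEpochs))
}

#' Locate the MMN peak
#'
#' Finds the most negative deflection of a difference wave within the
#' search window (default 100-250 ms, bracketing the typical 175-200 ms MMN
#' latencies). Ties are broken toward the earliest latency; a minimum
#' sitting on a window edge is flagged `edge_peak` since it may continue
#' outside the window.
#'
#' @param mmn a [Waveform-class] (typically a difference wave).
#' @param searchWindowMs two-element window, ms; must lie inside the
#'   waveform's time axis.
#' @return list with `latency_ms`, `value_uv` and logical `edge_peak`.
#' @export
findPeak <- function(mmn, searchWindowMs = c(100, 250)) {
  stopifnot(is(mmn, "Waveform"))
  if (searchWindowMs[1] >= searchWindowMs[2])
    stopf("empty search window")
  if (searchWindowMs[1] < min(mmn@times) || searchWindowMs[2] > max(mmn@times))
    stopf("search window [%g, %g] ms outside the epoch [%g, %g] ms",
          searchWindowMs[1], searchWindowMs[2], min(mmn@times), max(mmn@times))
  sel <- which(mmn@times >= searchWindowMs[1] & mmn@times <= searchWindowMs[2])
  v <- mmn@values[sel]
  i <- which.min(v)  # which.min returns the first (earliest) minimum on ties
  list(latency_ms = mmn@times[sel[i]], value_uv = v[i],
       edge_peak = i == 1L || i == length(sel))
}

#' Mean amplitude over a window centered at the peak
#'
#' Mean voltage across a fixed-width window (default 40 ms) centered at the
#' given peak latency, the standard MMN amplitude measure. The window is
#' closed on both ends on the sample grid (21 samples at 500 Hz) and must
#' lie entirely inside the epoch; a latency too close to the epoch end is
#' an error rather than a silently truncated window.
#'
#' @param mmn a [Waveform-class].
#' @param latencyMs window center, ms (usually from [findPeak()]).
#' @param windowMs full window width, ms.
#' @return mean amplitude in uV, with attribute `n_samples`.
#' @export
peakWindowAmplitude <- function(mmn, latencyMs, windowMs = 40) {
  stopifnot(is(mmn, "Waveform"))
  half <- windowMs / 2
  if (latencyMs - half < min(mmn@times) || latencyMs + half > max(mmn@times))
    stopf("the %g-ms window centered at %g ms extends outside the epoch [%g, %g] ms",
          windowMs, latencyMs, min(mmn@times), max(mmn@times))
  sel <- mmn@times >= latencyMs - half & mmn@times <= latencyMs + half
  out <- mean(mmn@values[sel])
  attr(out, "n_samples") <- sum(sel)
  out
}

#' Measure MMN peak latency and peak-window amplitude
#'
#' Applies [findPeak()] and [peakWindowAmplitude()] to one difference wave
#' and returns a one-row data.frame suitable for stacking into a results
#' table (one row per participant x contrast x session).
#'
#' @param mmn a difference [Waveform-class].
#' @param searchWindowMs peak search window, ms.
#' @param windowMs amplitude window width, ms.
#' @param contrast optional contrast name (e.g. `"phoneme"`, `"tone"`).
#' @return data.frame with columns `contrast`, `label`, `method`,
#'   `session`, `channel`, `peak_latency_ms`, `peak_amplitude_uv`,
#'   `n_epochs`, `edge_peak`.
#' @export
measureMmn <- function(mmn, searchWindowMs = c(100, 250), windowMs = 40,
                       contrast = NA_character_) {
  pk <- findPeak(mmn, searchWindowMs)
  amp <- peakWindowAmplitude(mmn, pk$latency_ms, windowMs)
  data.frame(contrast = contrast, label = mmn@label, method = mmn@method,
             session = mmn@session, channel = mmn@channel,
             peak_latency_ms = pk$latency_ms,
             peak_amplitude_uv = as.numeric(amp),
             n_epochs = mmn@nEpochs, edge_peak = pk$edge_peak,
             stringsAsFactors = FALSE)
}
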