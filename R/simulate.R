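#' The 11-electrode montage
#'
#' Channel names of the fronto-central montage used throughout: five midline
#' sites (Fz, FCz, Cz, CPz, Pz), four lateral sites (F1, F2, P1, P2) and the
#' left/right mastoids (M1, M2). `mastoidChannels()` returns the mastoid
#' pair used for re-referencing.
#'
#' @return character vector of channel names.
#' @export
eegMontage <- function() {
  c("Fz", "FCz", "Cz", "CPz", "Pz", "F1", "F2", "P1", "P2", "M1", "M2")
}

#' @rdname eegMontage
#' @export
mastoidChannels <- function() c("M1", "M2")

# Fronto-central scalp topography: maximal at FCz, attenuated toward
# parietal sites, polarity-inverted at the mastoids (weight -0.2) as for
# auditory generators, so mastoid re-referencing *increases* the
# fronto-central amplitude by a factor 1.2.
frontoCentralWeights <- function(channels = eegMontage()) {
  w <- c(Fz = 0.9, FCz = 1, Cz = 0.9, CPz = 0.7, Pz = 0.5,
         F1 = 0.85, F2 = 0.85, P1 = 0.45, P2 = 0.45, M1 = -0.2, M2 = -0.2)
  out <- w[channels]
  out[is.na(out)] <- 0
  stats::setNames(out, channels)
}

#' Construct a parametric ERP component
#'
#' @param peakLatencyMs peak latency, ms post stimulus onset.
#' @param widthMs Gaussian envelope SD, ms.
#' @param amplitudeUv signed amplitude at FCz, uV.
#' @param channelWeights named per-channel gains in \[-1, 1\]; defaults to
#'   the fronto-central topography with mastoid inversion.
#' @return an [ErpComponent-class].
#' @export
erpComponent <- function(peakLatencyMs, widthMs, amplitudeUv,
                         channelWeights = frontoCentralWeights()) {
  new("ErpComponent", peakLatencyMs = peakLatencyMs, widthMs = widthMs,
      amplitudeUv = amplitudeUv, channelWeights = channelWeights)
}

#' Construct a per-syllable ERP template
#'
#' @param label syllable label.
#' @param components list of [ErpComponent-class] rendered for every
#'   occurrence (the obligatory exogenous response).
#' @param contextMmn optional [ErpComponent-class] (amplitude <= 0) added
#'   only when the syllable occurs as a deviant in an oddball sequence.
#' @return an [ErpTemplate-class].
#' @export
erpTemplate <- function(label, components = list(), contextMmn = NULL) {
  new("ErpTemplate", label = label, components = components,
      contextMmn = contextMmn)
}

#' Default ERP templates for the three-syllable design
#'
#' All three syllables share the same exogenous response (an N1-like
#' negativity at 100 ms and a P2-like positivity at 200 ms), so traditional
#' and identity MMN estimates coincide under the defaults. Context MMN
#' components peak at 185 ms (within the 175-200 ms range typical of these
#' contrasts) with the tone deviant (`da4`, -6 uV) about twice as large as
#' the phoneme deviant (`ba1`, -2.5 uV).
#'
#' @param mmnAmplitudes named amplitudes (uV, <= 0) of the context MMN per
#'   deviant label.
#' @param mmnLatencyMs context MMN peak latency, ms.
#' @param mmnWidthMs context MMN envelope SD, ms.
#' @param channels montage for the channel weights.
#' @return named list of [ErpTemplate-class], one per label.
#' @export
defaultErpTemplates <- function(mmnAmplitudes = c(ba1 = -2.5, da4 = -6),
                                mmnLatencyMs = 185, mmnWidthMs = 25,
                                channels = eegMontage()) {
  w <- frontoCentralWeights(channels)
  exo <- list(
    erpComponent(100, 20, -3, w),
    erpComponent(200, 30, 2, w)
  )
  tpl <- list(da1 = erpTemplate("da1", exo))
  for (lab in names(mmnAmplitudes)) {
    tpl[[lab]] <- erpTemplate(lab, exo,
      contextMmn = erpComponent(mmnLatencyMs, mmnWidthMs,
                                mmnAmplitudes[[lab]], w))
  }
  tpl
}

#' Simulation configuration constructor
#'
#' @param fsHz acquisition sampling rate, Hz.
#' @param channels montage.
#' @param noiseSdUv background-noise SD, uV (broadband, before filtering).
#' @param noiseExponent 1/f^alpha spectral slope (0 = white, 1 = pink).
#' @param tmsSuppression factor in \[0, 1\] multiplying context MMN
#'   amplitudes in post-TMS sessions (1 = no suppression).
#' @param trialJitterSd SD of the per-trial multiplicative amplitude factor.
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(fsHz = 1000, channels = eegMontage(),
                             noiseSdUv = 10, noiseExponent = 1,
                             tmsSuppression = 0.7, trialJitterSd = 0.1,
                             seed = 1) {
  new("SimulationConfig", fsHz = fsHz, channels = channels,
      noiseSdUv = noiseSdUv, noiseExponent = noiseExponent,
      tmsSuppression = tmsSuppression, trialJitterSd = trialJitterSd,
      seed = seed)
}

# 1/f^alpha Gaussian noise via spectral shaping; returns n samples with the
# requested SD. alpha = 0 gives white noise. Caller controls the RNG state.
oneOverFNoise <- function(n, sdUv, alpha) {
  if (sdUv == 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (alpha == 0) return(x * sdUv)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # symmetric frequency index, keeps output real
  w <- ifelse(f == 0, 0, f^(-alpha / 2))
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  y / stats::sd(y) * sdUv
}

#' Render the single-trial ERP of a template
#'
#' Sums the template's Gaussian-enveloped components, scaled by the
#' per-channel weights, on the requested time grid (half-open
#' `[tRangeMs[1], tRangeMs[2])`). The context MMN component is included only
#' when `asDeviant = TRUE`, and is additionally scaled by `suppression`
#' (the post-TMS factor).
#'
#' @param template an [ErpTemplate-class].
#' @param asDeviant logical; is the syllable occurring as an oddball
#'   deviant?
#' @param fsHz sampling rate, Hz.
#' @param channels channel names to render.
#' @param tRangeMs time range, ms (default 0-300).
#' @param suppression factor applied to the context MMN amplitude.
#' @return channels x samples matrix (uV); sample times as attribute
#'   `"times"`.
#' @export
renderErp <- function(template, asDeviant = FALSE, fsHz = 1000,
                      channels = eegMontage(), tRangeMs = c(0, 300),
                      suppression = 1) {
  stopifnot(is(template, "ErpTemplate"))
  validObject(template)
  dt <- 1000 / fsHz
  times <- seq(tRangeMs[1], tRangeMs[2] - dt, by = dt)
  out <- matrix(0, nrow = length(channels), ncol = length(times),
                dimnames = list(channels, NULL))
  comps <- template@components
  if (asDeviant && !is.null(template@contextMmn)) {
    cm <- template@contextMmn
    cm@amplitudeUv <- cm@amplitudeUv * suppression
    comps <- c(comps, cm)
  }
  for (comp in comps) {
    env <- comp@amplitudeUv *
      exp(-(times - comp@peakLatencyMs)^2 / (2 * comp@widthMs^2))
    w <- comp@channelWeights[channels]
    w[is.na(w)] <- 0
    out <- out + outer(as.numeric(w), env)
  }
  attr(out, "times") <- times
  out
}

#' Simulate a continuous EEG recording
#'
#' Produces a continuous multi-channel recording as 1/f^alpha background
#' noise (independent across channels) plus single-trial ERPs superposed at
#' the event onsets. The ERP of each trial is the label's template rendered
#' over 0-400 ms; its context MMN component is included only for deviant
#' events in oddball sequences, and is scaled by the configuration's
#' `tmsSuppression` when `session = "post_tms"`. Per-trial amplitudes are
#' jittered multiplicatively (`1 + N(0, trialJitterSd)`, truncated at 0).
#' The recording starts `padMs` before the first onset and ends `padMs`
#' after the last trial window, so every event has full epoch support.
#' Identical configuration and seed give identical recordings.
#'
#' @param eventTable an [EventTable-class]; every label must have a
#'   template.
#' @param templates named list of [ErpTemplate-class].
#' @param config a [SimulationConfig-class].
#' @param session `"no_tms"` or `"post_tms"`.
#' @param padMs pre/post padding, ms (default 500).
#' @return a [Recording-class] referenced to the nose tip.
#' @examples
#' des <- oddballDesign(nTotal = 20, seed = 2)
#' rec <- simulateRecording(generateOddballSequence(des),
#'                          defaultErpTemplates(),
#'                          simulationConfig(noiseSdUv = 2, seed = 2))
#' @export
simulateRecording <- function(eventTable, templates,
                              config = simulationConfig(),
                              session = c("no_tms", "post_tms"),
                              padMs = 500) {
  stopifnot(is(eventTable, "EventTable"))
  session <- match.arg(session)
  validObject(config)
  ev <- eventTable@events
  missing <- setdiff(unique(ev$label), names(templates))
  if (length(missing) > 0)
    stopf("no ERP template for label(s): %s", paste(missing, collapse = ", "))
  fs <- config@fsHz
  dt <- 1000 / fs
  trialSpanMs <- 400
  startMs <- min(ev$onset_ms) - padMs
  endMs <- max(ev$onset_ms) + trialSpanMs + padMs
  n <- round((endMs - startMs) / dt)
  channels <- config@channels
  suppression <- if (session == "post_tms") config@tmsSuppression else 1

  data <- withSeed(config@seed, {
    d <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))
    for (i in seq_along(channels))
      d[i, ] <- oneOverFNoise(n, config@noiseSdUv, config@noiseExponent)
    jitter <- pmax(0, 1 + stats::rnorm(nrow(ev), sd = config@trialJitterSd))
    # render each (label, deviant-context) combination once, reuse per trial
    cache <- list()
    for (r in seq_len(nrow(ev))) {
      lab <- ev$label[r]
      asDev <- eventTable@labelRoles[[lab]] == "deviant" &&
        ev$sequence_kind[r] == "oddball"
      key <- paste(lab, asDev)
      if (is.null(cache[[key]])) {
        cache[[key]] <- renderErp(templates[[lab]], asDeviant = asDev,
                                  fsHz = fs, channels = channels,
                                  tRangeMs = c(0, trialSpanMs),
                                  suppression = suppression)
      }
      erp <- cache[[key]]
      at <- nearestSampleTiesDown((ev$onset_ms[r] - startMs) / dt) + 1
      idx <- at:(at + ncol(erp) - 1)
      d[, idx] <- d[, idx] + erp * jitter[r]
    }
    d
  })
  new("Recording", data = data, fsHz = fs, channelNames = channels,
      reference = "nose tip", startMs = startMs, events = eventTable)
}

#' Inject square artifact transients into a recording
#'
#' Adds a square pulse of the given amplitude to the listed events' future
#' epoch windows (50-150 ms post onset, on the FCz channel if present),
#' leaving every other sample untouched. Used to exercise the
#' absolute-amplitude artifact rejection rule with known ground truth.
#'
#' @param recording a [Recording-class].
#' @param eventIndices 0-based event `index` values to corrupt (may be
#'   empty, in which case the recording is returned unchanged).
#' @param amplitudeUv pulse amplitude, uV; must be nonzero.
#' @param channel channel receiving the pulse.
#' @return the corrupted [Recording-class].
#' @export
injectArtifacts <- function(recording, eventIndices, amplitudeUv,
                            channel = "FCz") {
  stopifnot(is(recording, "Recording"))
  if (length(eventIndices) == 0) return(recording)
  if (amplitudeUv == 0) stopf("amplitudeUv must be nonzero")
  ev <- recording@events@events
  bad <- setdiff(eventIndices, ev$index)
  if (length(bad) > 0)
    stopf("event index out of range: %s", paste(bad, collapse = ", "))
  if (!(channel %in% recording@channelNames))
    stopf("channel '%s' not in the recording", channel)
  ch <- match(channel, recording@channelNames)
  dt <- 1000 / recording@fsHz
  for (ei in eventIndices) {
    onset <- ev$onset_ms[ev$index == ei]
    from <- nearestSampleTiesDown((onset + 50 - recording@startMs) / dt) + 1
    to <- nearestSampleTiesDown((onset + 150 - recording@startMs) / dt)
    recording@data[ch, from:to] <- recording@data[ch, from:to] + amplitudeUv
  }
  recording
}
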