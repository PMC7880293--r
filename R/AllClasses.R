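#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Oddball sequence design
#'
#' Parameters of a passive auditory oddball (or same-stimulus control)
#' sequence: how many stimuli, with what per-label probabilities, at what
#' stimulus-onset asynchrony, and under which pseudorandomization constraint.
#' Probabilities are exact proportions: `nTotal * p` must be a whole number
#' for every label, so per-label event counts are identical across seeds.
#'
#' @slot nTotal total number of stimuli in the sequence.
#' @slot probabilities named numeric vector of per-label presentation
#'   probabilities; must sum to 1.
#' @slot standard name of the frequent (standard) syllable; all other labels
#'   are deviants.
#' @slot stimulusDurationMs stimulus duration in ms.
#' @slot isiMs offset-to-onset inter-stimulus interval in ms; the
#'   stimulus-onset asynchrony is `stimulusDurationMs + isiMs`.
#' @slot minStandardsBetweenDeviants minimum number of standards between two
#'   successive deviants (0 = unconstrained).
#' @slot seed integer seed for the pseudorandomization.
#' @export
setClass("SequenceDesign",
  representation(
    nTotal = "numeric",
    probabilities = "numeric",
    standard = "character",
    stimulusDurationMs = "numeric",
    isiMs = "numeric",
    minStandardsBetweenDeviants = "numeric",
    seed = "numeric"
  )
)

setValidity("SequenceDesign", function(object) {
  p <- object@probabilities
  if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
    return("probabilities must be uniquely named by syllable label")
  if (abs(sum(p) - 1) > 1e-12)
    return("probabilities must sum to 1 (within 1e-12)")
  if (any(p < 0)) return("probabilities must be non-negative")
  counts <- object@nTotal * p
  if (any(abs(counts - round(counts)) > 1e-9))
    return("exact-count design: nTotal * probability must be an integer for every label")
  if (!(object@standard %in% names(p)))
    return(sprintf("standard label '%s' not among probability names", object@standard))
  if (object@stimulusDurationMs <= 0) return("stimulusDurationMs must be > 0")
  if (object@isiMs < 0) return("isiMs must be >= 0")
  if (object@minStandardsBetweenDeviants < 0 ||
      object@minStandardsBetweenDeviants != round(object@minStandardsBetweenDeviants))
    return("minStandardsBetweenDeviants must be a non-negative integer")
  TRUE
})

#' Ordered table of stimulus events
#'
#' The backbone object tying design, simulation and epoching together: one
#' row per stimulus with its onset (ms from sequence start), syllable label,
#' sequence kind (`oddball` or `control`) and 0-based position. Onsets lie on
#' the fixed stimulus-onset-asynchrony grid: event `i` starts at
#' `i * (stimulusDurationMs + isiMs)`.
#'
#' @slot events data.frame with columns `onset_ms`, `label`,
#'   `sequence_kind`, `index`.
#' @slot stimulusDurationMs stimulus duration in ms.
#' @slot isiMs inter-stimulus interval (offset to onset) in ms.
#' @slot labelRoles named character vector mapping each label to its role in
#'   the oddball design (`"standard"` or `"deviant"`).
#' @export
setClass("EventTable",
  representation(
    events = "data.frame",
    stimulusDurationMs = "numeric",
    isiMs = "numeric",
    labelRoles = "character"
  )
)

setValidity("EventTable", function(object) {
  ev <- object@events
  need <- c("onset_ms", "label", "sequence_kind", "index")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ev) > 0) {
    if (any(diff(ev$onset_ms) <= 0)) return("onsets must be strictly increasing")
    soa <- object@stimulusDurationMs + object@isiMs
    if (any(abs(ev$onset_ms - ev$index * soa) > 1e-9))
      return("onset of event i must equal i * (stimulusDurationMs + isiMs)")
    if (!all(ev$label %in% names(object@labelRoles)))
      return("all event labels must have a role in labelRoles")
  }
  if (sum(object@labelRoles == "standard") != 1)
    return("exactly one label must have role 'standard'")
  TRUE
})

#' Parametric ERP component
#'
#' One event-related potential component modelled as a Gaussian temporal
#' envelope: `amplitudeUv * exp(-(t - peakLatencyMs)^2 / (2 * widthMs^2))`,
#' scaled per channel by `channelWeights`. The FCz weight is 1 by convention
#' so `amplitudeUv` is the amplitude at the fronto-central reference site;
#' mastoid weights may be negative (polarity inversion of auditory
#' components below the Sylvian fissure).
#'
#' @slot peakLatencyMs latency of the envelope peak, ms post stimulus onset.
#' @slot widthMs standard deviation of the Gaussian envelope, ms.
#' @slot amplitudeUv signed amplitude at FCz, microvolts.
#' @slot channelWeights named numeric gains in \[-1, 1\] per channel.
#' @export
setClass("ErpComponent",
  representation(
    peakLatencyMs = "numeric",
    widthMs = "numeric",
    amplitudeUv = "numeric",
    channelWeights = "numeric"
  )
)

setValidity("ErpComponent", function(object) {
  if (object@widthMs <= 0) return("widthMs must be > 0")
  w <- object@channelWeights
  if (is.null(names(w))) return("channelWeights must be named by channel")
  if ("FCz" %in% names(w) && abs(w[["FCz"]] - 1) > 1e-12)
    return("FCz weight must be 1 by convention")
  if (any(abs(w) > 1 + 1e-12)) return("channel weights must lie in [-1, 1]")
  TRUE
})

setClassUnion("ErpComponentOrNULL", c("ErpComponent", "NULL"))

#' Per-syllable ERP template
#'
#' The obligatory exogenous response a syllable evokes regardless of context,
#' plus an optional context-dependent MMN component that is added only when
#' the syllable occurs as a deviant in an oddball sequence. The contextual
#' component must be a negativity (amplitude <= 0).
#'
#' @slot label syllable label the template belongs to.
#' @slot components list of [ErpComponent-class] rendered for every
#'   occurrence of the syllable.
#' @slot contextMmn [ErpComponent-class] or `NULL`; rendered only in deviant
#'   (oddball) context, and scaled by the TMS suppression factor in post-TMS
#'   sessions.
#' @export
setClass("ErpTemplate",
  representation(
    label = "character",
    components = "list",
    contextMmn = "ErpComponentOrNULL"
  )
)

setValidity("ErpTemplate", function(object) {
  if (!all(vapply(object@components, is, logical(1), class2 = "ErpComponent")))
    return("components must all be ErpComponent objects")
  if (!is.null(object@contextMmn) && object@contextMmn@amplitudeUv > 0)
    return("contextMmn amplitude must be <= 0 (the MMN is a negativity)")
  TRUE
})

#' EEG simulation configuration
#'
#' Acquisition-level parameters of the synthetic EEG generator: montage,
#' sampling rate, background-noise model and single-trial variability, plus
#' the multiplicative suppression applied to context MMN components in
#' post-TMS sessions.
#'
#' @slot fsHz acquisition sampling rate, Hz (default 1000).
#' @slot channels ordered channel names (default the 11-electrode montage,
#'   see [eegMontage()]).
#' @slot noiseSdUv standard deviation of the broadband background noise, uV.
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha noise
#'   (0 = white).
#' @slot tmsSuppression multiplicative factor in \[0, 1\] applied to context
#'   MMN amplitudes in post-TMS sessions.
#' @slot trialJitterSd SD of the per-trial multiplicative amplitude factor
#'   (fraction of 1; 0 = identical trials).
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig",
  representation(
    fsHz = "numeric",
    channels = "character",
    noiseSdUv = "numeric",
    noiseExponent = "numeric",
    tmsSuppression = "numeric",
    trialJitterSd = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@fsHz <= 0) return("fsHz must be > 0")
  if (length(object@channels) < 1) return("at least one channel required")
  if (anyDuplicated(object@channels)) return("channel names must be unique")
  if (object@noiseSdUv < 0) return("noiseSdUv must be >= 0")
  if (object@tmsSuppression < 0 || object@tmsSuppression > 1)
    return("tmsSuppression must lie in [0, 1]")
  if (object@trialJitterSd < 0) return("trialJitterSd must be >= 0")
  TRUE
})

#' Continuous multi-channel EEG recording
#'
#' A channel-by-sample voltage matrix in microvolts with its sampling rate,
#' reference description and attached [EventTable-class]. The recording may
#' begin before the first stimulus: `startMs` is the time of the first
#' sample on the event-table clock (so a value of -500 gives every event a
#' pre-stimulus baseline).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fsHz sampling rate, Hz.
#' @slot channelNames character vector, one per matrix row.
#' @slot reference free-text description of the reference (e.g. "nose tip").
#' @slot startMs time of the first sample, ms, on the event-onset clock.
#' @slot events attached [EventTable-class].
#' @export
setClass("Recording",
  representation(
    data = "matrix",
    fsHz = "numeric",
    channelNames = "character",
    reference = "character",
    startMs = "numeric",
    events = "EventTable"
  )
)

setValidity("Recording", function(object) {
  if (nrow(object@data) != length(object@channelNames))
    return("data must have one row per channel name")
  if (object@fsHz <= 0) return("fsHz must be > 0")
  ev <- object@events@events
  if (nrow(ev) > 0) {
    endMs <- object@startMs + (ncol(object@data) - 1) * 1000 / object@fsHz
    if (any(ev$onset_ms < object@startMs) || any(ev$onset_ms > endMs))
      return("all events must fall inside the recording")
  }
  TRUE
})

#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain applied to a continuous recording:
#' resampling target, re-reference channels, band-pass edges, epoch window,
#' artifact-rejection threshold and the count of sequence-initial stimuli to
#' exclude.
#'
#' @slot targetFsHz analysis sampling rate, Hz (default 500).
#' @slot rerefChannels channels averaged to form the new reference (default
#'   the two mastoids, `M1`/`M2`).
#' @slot highpassHz high-pass edge, Hz (default 1).
#' @slot lowpassHz low-pass edge, Hz (default 30).
#' @slot epochStartMs epoch start relative to stimulus onset, ms (default
#'   -100).
#' @slot epochEndMs epoch end (exclusive) relative to onset, ms (default
#'   300); the window is half-open on the analysis grid, so the default
#'   gives 200 samples at 500 Hz.
#' @slot rejectThresholdUv absolute-amplitude rejection threshold, uV
#'   (default 70); comparison is strict (rejects only above the threshold).
#' @slot nInitialExcluded number of sequence-initial epochs excluded by
#'   design (default 10).
#' @slot filterOrder Butterworth section order used for the band-pass before
#'   forward-backward application (default 4).
#' @export
setClass("PreprocessConfig",
  representation(
    targetFsHz = "numeric",
    rerefChannels = "character",
    highpassHz = "numeric",
    lowpassHz = "numeric",
    epochStartMs = "numeric",
    epochEndMs = "numeric",
    rejectThresholdUv = "numeric",
    nInitialExcluded = "numeric",
    filterOrder = "numeric"
  )
)

setValidity("PreprocessConfig", function(object) {
  if (!(object@highpassHz < object@lowpassHz))
    return("highpassHz must be below lowpassHz")
  if (object@lowpassHz >= object@targetFsHz / 2)
    return("lowpassHz must be below the analysis Nyquist frequency")
  if (!(object@epochStartMs < 0 && 0 < object@epochEndMs))
    return("epoch window must straddle stimulus onset (epochStartMs < 0 < epochEndMs)")
  if (object@rejectThresholdUv <= 0) return("rejectThresholdUv must be > 0")
  if (object@nInitialExcluded < 0) return("nInitialExcluded must be >= 0")
  TRUE
})

#' Set of fixed-length epochs
#'
#' Per-event voltage segments cut from a recording, baseline-corrected, with
#' a per-epoch status. Every input event appears exactly once with exactly
#' one status: `kept`, `artifact_rejected` or `design_excluded` (the
#' `reason` column separates initial-stimulus, post-deviant and boundary
#' exclusions). The time axis is half-open, `[epochStartMs, epochEndMs)`, on
#' the analysis sampling grid.
#'
#' @slot data numeric array, epochs x channels x samples, microvolts.
#' @slot times sample times, ms relative to stimulus onset.
#' @slot fsHz analysis sampling rate, Hz.
#' @slot channelNames channel names, one per second-dimension slice.
#' @slot info data.frame with one row per epoch: `index`, `label`, `role`,
#'   `sequence_kind`, `status`, `reason`.
#' @slot provenance list echoing the configuration that produced the set.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    fsHz = "numeric",
    channelNames = "character",
    info = "data.frame",
    provenance = "list"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-d array (epoch x channel x sample)")
  if (d[1] != nrow(object@info)) return("one info row per epoch required")
  if (d[2] != length(object@channelNames)) return("one channel name per channel slice")
  if (d[3] != length(object@times)) return("one time per sample slice")
  ok <- c("kept", "artifact_rejected", "design_excluded")
  if (nrow(object@info) > 0 && !all(object@info$status %in% ok))
    return(sprintf("status must be one of %s", paste(ok, collapse = ", ")))
  TRUE
})

#' Averaged waveform
#'
#' A single averaged time series (uV versus ms) for one channel and one
#' condition; the difference of two Waveforms is an MMN wave. Metadata
#' records what was averaged and how many epochs went in.
#'
#' @slot values voltages, uV, one per sample.
#' @slot times sample times, ms relative to stimulus onset.
#' @slot fsHz sampling rate of the analysis grid, Hz.
#' @slot channel channel name.
#' @slot label syllable label (for difference waves, the deviant's label).
#' @slot sequenceKind `oddball`, `control`, or `difference`.
#' @slot session session tag (e.g. `no_tms`, `post_tms`), or `NA`.
#' @slot method `average`, `traditional` or `identity`.
#' @slot nEpochs number of epochs averaged (>= 1).
#' @export
setClass("Waveform",
  representation(
    values = "numeric",
    times = "numeric",
    fsHz = "numeric",
    channel = "character",
    label = "character",
    sequenceKind = "character",
    session = "character",
    method = "character",
    nEpochs = "numeric"
  )
)

setValidity("Waveform", function(object) {
  if (length(object@values) != length(object@times))
    return("values and times must have equal length")
  if (object@nEpochs < 1) return("nEpochs must be >= 1")
  TRUE
})

#' Pointwise test result with run-length criterion
#'
#' Pointwise paired-t statistics and two-tailed p values over the epoch time
#' axis, together with the maximal runs of consecutive samples with
#' `p < alpha` that reach the run-length criterion of at least `k` samples
#' (10 samples = 20 ms at 500 Hz). `runs` has columns `start_ms`, `end_ms`
#' (times of the first and last sample in the run), `n_samples` and
#' `length_ms` (`n_samples` times the sampling step).
#'
#' @slot times sample times, ms.
#' @slot statistic pointwise paired t values.
#' @slot p pointwise two-tailed p values.
#' @slot runs data.frame of significant runs (possibly 0 rows).
#' @slot alpha pointwise significance level.
#' @slot k minimum run length in samples.
#' @slot n number of participants (pairs).
#' @export
setClass("WindowTestResult",
  representation(
    times = "numeric",
    statistic = "numeric",
    p = "numeric",
    runs = "data.frame",
    alpha = "numeric",
    k = "numeric",
    n = "numeric"
  )
)

setValidity("WindowTestResult", function(object) {
  if (length(object@times) != length(object@p) ||
      length(object@times) != length(object@statistic))
    return("times, statistic and p must have equal length")
  if (nrow(object@runs) > 0 && any(object@runs$n_samples < object@k))
    return("every reported run must have length >= k samples")
  TRUE
})
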