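#' Accessors for mmnerp objects
#'
#' Small accessor layer over the S4 containers: `channelNames()` and
#' `samplingRate()` for recordings and epoch sets, `voltages()` for the raw
#' numeric payload (channel x sample matrix, epoch x channel x sample array,
#' or waveform vector), `events()` / `nEvents()` / `labelRoles()` for event
#' tables, `sampleTimes()` for time axes, `epochInfo()` for the per-epoch
#' status manifest and `significantRuns()` for run-length test results.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value; see class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("channelNames", "Recording", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@fsHz)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fsHz)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Waveform", function(x) x@fsHz)

#' @rdname accessors
#' @export
setMethod("voltages", "Recording", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voltages", "EpochSet", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voltages", "Waveform", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("events", "Recording", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("events", "EventTable", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setMethod("nEvents", "Recording", function(x) nrow(x@events@events))

#' @rdname accessors
#' @export
setMethod("labelRoles", "EventTable", function(x) x@labelRoles)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "EpochSet", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "Waveform", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "WindowTestResult", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)

#' @rdname accessors
#' @export
setMethod("significantRuns", "WindowTestResult", function(x) x@runs)

setMethod("show", "SequenceDesign", function(object) {
  cat("SequenceDesign:", object@nTotal, "stimuli, SOA",
      object@stimulusDurationMs + object@isiMs, "ms\n")
  p <- object@probabilities
  cat("  labels:", paste(sprintf("%s=%.3g%s", names(p), p,
      ifelse(names(p) == object@standard, " (standard)", "")), collapse = ", "), "\n")
  cat("  min standards between deviants:", object@minStandardsBetweenDeviants,
      " seed:", object@seed, "\n")
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat("EventTable:", nrow(ev), "events")
  if (nrow(ev) > 0) {
    cat(" (", paste(sprintf("%s=%d", names(table(ev$label)), as.integer(table(ev$label))),
        collapse = ", "), ")", sep = "")
    cat(", kind:", paste(unique(ev$sequence_kind), collapse = "/"))
  }
  cat("\n  SOA:", object@stimulusDurationMs + object@isiMs, "ms\n")
})

setMethod("show", "Recording", function(object) {
  cat("Recording:", length(object@channelNames), "channels x",
      ncol(object@data), "samples @", object@fsHz, "Hz\n")
  cat("  span:", object@startMs, "to",
      round(object@startMs + (ncol(object@data) - 1) * 1000 / object@fsHz), "ms;",
      "reference:", object@reference, "\n")
  cat("  events:", nrow(object@events@events), "\n")
})

setMethod("show", "EpochSet", function(object) {
  st <- table(factor(object@info$status,
                     levels = c("kept", "artifact_rejected", "design_excluded")))
  cat("EpochSet:", dim(object@data)[1], "epochs x", dim(object@data)[2],
      "channels x", dim(object@data)[3], "samples @", object@fsHz, "Hz\n")
  cat("  window: [", min(object@times), ",", max(object@times) + 1000 / object@fsHz,
      ") ms;  kept:", st[["kept"]], " rejected:", st[["artifact_rejected"]],
      " excluded:", st[["design_excluded"]], "\n")
})

setMethod("show", "Waveform", function(object) {
  cat("Waveform:", object@channel, "|", object@label, "|", object@sequenceKind,
      "|", object@method, "| session:", object@session, "\n")
  cat("  ", length(object@values), "samples,",
      min(object@times), "to", max(object@times), "ms, n epochs:",
      object@nEpochs, "\n")
})

setMethod("show", "WindowTestResult", function(object) {
  cat("WindowTestResult: pointwise paired t,", length(object@times),
      "samples, n =", object@n, "\n")
  cat("  alpha:", object@alpha, " run criterion: >=", object@k, "samples\n")
  if (nrow(object@runs) == 0) {
    cat("  no significant runs\n")
  } else {
    for (i in seq_len(nrow(object@runs)))
      cat(sprintf("  run %d: %g-%g ms (%d samples)\n", i,
                  object@runs$start_ms[i], object@runs$end_ms[i],
                  object@runs$n_samples[i]))
  }
})
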