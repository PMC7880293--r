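#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("labelRoles", function(x) standardGeneric("labelRoles"))

#' @rdname accessors
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))

#' @rdname accessors
#' @export
setGeneric("significantRuns", function(x) standardGeneric("significantRuns"))
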