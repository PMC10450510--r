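#' @rdname UnitSet-accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname UnitSet-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname UnitSet-accessors
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' @rdname UnitSet-accessors
#' @export
setGeneric("waveformOf", function(x, unit) standardGeneric("waveformOf"))

#' @rdname UnitSet-accessors
#' @export
setGeneric("channelOf", function(x, unit) standardGeneric("channelOf"))

#' @rdname UnitSet-accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("spaLocation", function(x) standardGeneric("spaLocation"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("lfpgTraces", function(x) standardGeneric("lfpgTraces"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("muaTraces", function(x) standardGeneric("muaTraces"))

#' @rdname SPAEventSet-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochGaps", function(x) standardGeneric("epochGaps"))
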