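#' Accessors for UnitSet
#'
#' @param x a \linkS4class{UnitSet}.
#' @param unit a unit id.
#' @return \code{unitIds}: character vector of unit ids. \code{nUnits}:
#'   integer count. \code{spikeTimes}: numeric vector of spike times (s) of
#'   one unit. \code{waveformOf}: numeric mean waveform (microvolt) or NULL.
#'   \code{channelOf}: integer channel. \code{recordingDuration}: seconds.
#' @name UnitSet-accessors
NULL

#' @rdname UnitSet-accessors
#' @export
setMethod("unitIds", "UnitSet", function(x) {
    ids <- unique(c(x@spikes$unit_id, names(x@channels), names(x@waveforms)))
    as.character(ids)
})

#' @rdname UnitSet-accessors
#' @export
setMethod("nUnits", "UnitSet", function(x) length(unitIds(x)))

#' @rdname UnitSet-accessors
#' @export
setMethod("spikeTimes", "UnitSet", function(x, unit) {
    x@spikes$time_s[x@spikes$unit_id == unit]
})

#' @rdname UnitSet-accessors
#' @export
setMethod("waveformOf", "UnitSet", function(x, unit) x@waveforms[[unit]])

#' @rdname UnitSet-accessors
#' @export
setMethod("channelOf", "UnitSet", function(x, unit) {
    unname(x@channels[unit])
})

#' @rdname UnitSet-accessors
#' @export
setMethod("recordingDuration", "UnitSet", function(x) x@duration)

setMethod("show", "UnitSet", function(object) {
    cat(sprintf("UnitSet: %d unit(s), %d spike(s), %.1f s recording\n",
                nUnits(object), nrow(object@spikes), object@duration))
    if (length(object@waveforms))
        cat(sprintf("  mean waveforms at %g Hz (%d units)\n",
                    object@waveformRate, length(object@waveforms)))
})

#' Accessors for SPAEventSet
#'
#' @param x a \linkS4class{SPAEventSet}.
#' @return \code{eventTimes}: numeric event times (s). \code{nEvents}: count.
#'   \code{spaLocation}: layer label of the SPA. \code{lfpgTraces} /
#'   \code{muaTraces}: events x samples matrices (microvolt) or NULL.
#'   \code{traceTimes}: trace time base (ms).
#' @name SPAEventSet-accessors
NULL

#' @rdname SPAEventSet-accessors
#' @export
setMethod("eventTimes", "SPAEventSet", function(x) x@times)

#' @rdname SPAEventSet-accessors
#' @export
setMethod("nEvents", "SPAEventSet", function(x) length(x@times))

#' @rdname SPAEventSet-accessors
#' @export
setMethod("spaLocation", "SPAEventSet", function(x) x@location)

#' @rdname SPAEventSet-accessors
#' @export
setMethod("lfpgTraces", "SPAEventSet", function(x)
    if (nrow(x@lfpg)) x@lfpg else NULL)

#' @rdname SPAEventSet-accessors
#' @export
setMethod("muaTraces", "SPAEventSet", function(x)
    if (nrow(x@mua)) x@mua else NULL)

#' @rdname SPAEventSet-accessors
#' @export
setMethod("traceTimes", "SPAEventSet", function(x) x@traceTimes)

setMethod("show", "SPAEventSet", function(object) {
    cat(sprintf("SPAEventSet: %d event(s), %s location%s\n",
                nEvents(object), object@location,
                if (nrow(object@lfpg)) ", with LFPg/MUA traces" else ""))
})

#' Accessors for EpochSet
#'
#' @param x an \linkS4class{EpochSet}.
#' @return \code{epochs}: data.frame(label, start, end). \code{epochGaps}:
#'   data.frame of excluded intervals with a \code{why} column.
#' @name EpochSet-accessors
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)

#' @rdname EpochSet-accessors
#' @export
setMethod("epochGaps", "EpochSet", function(x) x@gaps)

setMethod("show", "EpochSet", function(object) {
    ep <- object@epochs
    cat(sprintf("EpochSet: %d epoch(s)\n", nrow(ep)))
    if (nrow(ep))
        for (i in seq_len(nrow(ep)))
            cat(sprintf("  %-9s %8.1f - %8.1f s (%.1f s)\n", ep$label[i],
                        ep$start[i], ep$end[i], ep$end[i] - ep$start[i]))
})

setMethod("show", "CrossCorrelogram", function(object) {
    cat(sprintf("CrossCorrelogram %s -> %s: %d bins, baseline %.2f +/- %.2f, n_ref = %d\n",
                object@ref, object@target, length(object@lags),
                object@baselineMean, object@baselineSD, object@nRef))
})
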