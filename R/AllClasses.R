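#' @import methods
NULL

#' UnitSet: sorted single units of one slice recording
#'
#' Container for the spike-sorting output consumed by every downstream stage:
#' per-unit spike times, mean action-potential waveforms and the laminar
#' channel each unit was detected on.
#'
#' @slot spikes data.frame with columns \code{unit_id} (character) and
#'   \code{time_s} (numeric, seconds); times are strictly increasing within
#'   each unit.
#' @slot channels named integer vector, channel (1-23) per unit id.
#' @slot waveforms named list of numeric vectors (mean waveform, microvolt),
#'   one per unit id; each has at least 32 samples. May be empty.
#' @slot duration numeric(1), recording duration in seconds.
#' @slot waveformRate numeric(1), waveform sampling rate in Hz.
#' @export
setClass("UnitSet",
    representation(spikes = "data.frame", channels = "integer",
                   waveforms = "list", duration = "numeric",
                   waveformRate = "numeric"),
    prototype(spikes = data.frame(unit_id = character(), time_s = numeric()),
              channels = integer(), waveforms = list(), duration = 0,
              waveformRate = 20000))

setValidity("UnitSet", function(object) {
    msg <- character()
    sp <- object@spikes
    if (!all(c("unit_id", "time_s") %in% names(sp)))
        return("spikes must have columns unit_id, time_s")
    if (nrow(sp)) {
        if (any(sp$time_s < 0) || any(sp$time_s > object@duration + 1e-9))
            msg <- c(msg, "spike times must lie in [0, duration]")
        bad <- vapply(split(sp$time_s, sp$unit_id),
                      function(t) any(diff(t) <= 0), logical(1))
        if (any(bad))
            msg <- c(msg, paste("spike times not strictly increasing for unit(s):",
                                paste(names(bad)[bad], collapse = ", ")))
    }
    ids <- unique(sp$unit_id)
    if (length(object@channels)) {
        if (is.null(names(object@channels)) || anyDuplicated(names(object@channels)))
            msg <- c(msg, "channels must be uniquely named by unit id")
        if (any(object@channels < 1L | object@channels > 23L))
            msg <- c(msg, "channels must be in [1, 23]")
    }
    if (length(object@waveforms)) {
        if (any(lengths(object@waveforms) < 32L))
            msg <- c(msg, "each waveform needs >= 32 samples")
    }
    if (length(object@duration) != 1L || object@duration < 0)
        msg <- c(msg, "duration must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' SPAEventSet: spontaneous population activity events of one SPA
#'
#' One SPA is the totality of recurring population bursts at one location of
#' one recording; each event's LFPg peak is its time zero. Optional per-event
#' LFPg and MUA trace windows share a common millisecond time base.
#'
#' @slot times numeric, ascending event times (s).
#' @slot location character(1), one of supragranular, granular, infragranular,
#'   mixed.
#' @slot lfpg,mua numeric matrix (events x samples) or 0-row matrix when
#'   traces were not stored; microvolt.
#' @slot traceTimes numeric, common trace time base in ms relative to the
#'   event's LFPg peak.
#' @export
setClass("SPAEventSet",
    representation(times = "numeric", location = "character",
                   lfpg = "matrix", mua = "matrix", traceTimes = "numeric"),
    prototype(times = numeric(), location = "supragranular",
              lfpg = matrix(numeric(), 0, 0), mua = matrix(numeric(), 0, 0),
              traceTimes = numeric()))

setValidity("SPAEventSet", function(object) {
    msg <- character()
    if (is.unsorted(object@times, strictly = FALSE))
        msg <- c(msg, "event times must be ascending")
    if (!object@location %in% c("supragranular", "granular", "infragranular", "mixed"))
        msg <- c(msg, "unknown location label")
    for (nm in c("lfpg", "mua")) {
        tr <- slot(object, nm)
        if (nrow(tr)) {
            if (nrow(tr) != length(object@times))
                msg <- c(msg, sprintf("%s needs one row per event", nm))
            if (ncol(tr) != length(object@traceTimes))
                msg <- c(msg, sprintf("%s columns must match traceTimes", nm))
        }
    }
    if (length(msg)) msg else TRUE
})

#' EpochSet: labelled pharmacological epochs
#'
#' Non-overlapping analysis intervals, one per bath condition, trimmed of
#' transition periods. Excluded intervals (guards and post-cap remainders)
#' are retained so that total annotated time is conserved.
#'
#' @slot epochs data.frame with columns \code{label} (control / APV /
#'   NBQX+APV / washout), \code{start}, \code{end} (s).
#' @slot gaps data.frame with columns \code{start}, \code{end}, \code{why}
#'   ("guard" or "overflow").
#' @export
setClass("EpochSet",
    representation(epochs = "data.frame", gaps = "data.frame"),
    prototype(epochs = data.frame(label = character(), start = numeric(),
                                  end = numeric()),
              gaps = data.frame(start = numeric(), end = numeric(),
                                why = character())))

epochLabels <- c("control", "APV", "NBQX+APV", "washout")

setValidity("EpochSet", function(object) {
    ep <- object@epochs
    msg <- character()
    if (!all(c("label", "start", "end") %in% names(ep)))
        return("epochs must have columns label, start, end")
    if (nrow(ep)) {
        if (!all(ep$label %in% epochLabels))
            msg <- c(msg, paste("labels must be in:", paste(epochLabels, collapse = ", ")))
        if (any(ep$end < ep$start))
            msg <- c(msg, "epoch end before start")
        o <- order(ep$start)
        if (any(ep$start[o][-1] < ep$end[o][-nrow(ep)] - 1e-9))
            msg <- c(msg, "epochs overlap")
        if (any(ep$end - ep$start > 300 + 1e-6))
            msg <- c(msg, "epochs longer than the 300 s target duration")
    }
    if (length(msg)) msg else TRUE
})

#' LayerMap: laminar channel-to-layer assignment
#'
#' Default geometry of the 24-contact laminar probe: channels 1-8
#' supragranular, 9-13 granular, 14-23 infragranular. Per-recording overrides
#' win over the defaults (channel positions are corrected per patient).
#'
#' @slot overrides named character vector, names are channel numbers.
#' @export
setClass("LayerMap", representation(overrides = "character"),
         prototype(overrides = character()))

setValidity("LayerMap", function(object) {
    ov <- object@overrides
    if (length(ov)) {
        ch <- suppressWarnings(as.integer(names(ov)))
        if (any(is.na(ch)) || any(ch < 1L | ch > 23L))
            return("override names must be channel numbers in 1..23")
        if (!all(ov %in% c("supragranular", "granular", "infragranular")))
            return("override values must be layer labels")
    }
    TRUE
})

#' CrossCorrelogram: spike-time crosscorrelogram of an ordered unit pair
#'
#' Lags are target minus reference times, binned at 1 ms over -40..+40 ms
#' (81 bins at integer-centred bins). Baseline mean/SD are computed over the
#' flank bins used by the detection rule.
#'
#' @slot ref,target character(1) unit ids.
#' @slot lags numeric, bin centres in ms.
#' @slot counts numeric, spike-pair counts per bin.
#' @slot baselineMean,baselineSD numeric(1).
#' @slot nRef integer(1), number of reference spikes.
#' @export
setClass("CrossCorrelogram",
    representation(ref = "character", target = "character", lags = "numeric",
                   counts = "numeric", baselineMean = "numeric",
                   baselineSD = "numeric", nRef = "integer"))

setValidity("CrossCorrelogram", function(object) {
    if (length(object@lags) != length(object@counts))
        return("lags and counts differ in length")
    if (identical(object@ref, object@target))
        return("self-correlogram is not a pair")
    TRUE
})
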