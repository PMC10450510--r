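#' Construct a UnitSet
#'
#' @param spikes data.frame with columns \code{unit_id}, \code{time_s} and
#'   optionally \code{channel}.
#' @param channels named integer vector (channel per unit id); taken from the
#'   \code{channel} column when absent.
#' @param waveforms named list of numeric mean waveforms (microvolt).
#' @param duration recording duration in s; defaults to the last spike time.
#' @param waveformRate waveform sampling rate in Hz.
#' @return a validated \linkS4class{UnitSet}; spike times are sorted per unit.
#' @examples
#' u <- UnitSet(data.frame(unit_id = "u1", time_s = c(0.1, 0.2, 0.3),
#'                         channel = 5L))
#' spikeTimes(u, "u1")
#' @export
UnitSet <- function(spikes, channels = NULL, waveforms = list(),
                    duration = NULL, waveformRate = 20000) {
    spikes$unit_id <- as.character(spikes$unit_id)
    if (is.null(channels) && "channel" %in% names(spikes) && nrow(spikes)) {
        first <- !duplicated(spikes$unit_id)
        channels <- structure(as.integer(spikes$channel[first]),
                              names = spikes$unit_id[first])
        conflicting <- vapply(split(spikes$channel, spikes$unit_id),
                              function(ch) length(unique(ch)) > 1L, logical(1))
        if (any(conflicting))
            stop("conflicting channel assignment for unit(s): ",
                 paste(names(conflicting)[conflicting], collapse = ", "))
    }
    if (nrow(spikes)) {
        dup <- vapply(split(spikes$time_s, spikes$unit_id),
                      function(t) anyDuplicated(t) > 0L, logical(1))
        if (any(dup))
            stop("duplicate spike timestamps within unit(s): ",
                 paste(names(dup)[dup], collapse = ", "))
        spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
        rownames(spikes) <- NULL
    }
    if (is.null(duration))
        duration <- if (nrow(spikes)) max(spikes$time_s) else 0
    new("UnitSet", spikes = spikes[, intersect(c("unit_id", "time_s"),
                                               names(spikes)), drop = FALSE],
        channels = if (is.null(channels)) integer() else channels,
        waveforms = waveforms, duration = as.numeric(duration),
        waveformRate = waveformRate)
}

#' Construct an SPAEventSet
#'
#' @param times ascending event times (s); each is the LFPg peak of one
#'   population event.
#' @param location layer label of the SPA (supragranular, granular,
#'   infragranular or mixed).
#' @param lfpg,mua optional events x samples trace matrices (microvolt).
#' @param traceTimes trace time base in ms relative to each event's peak.
#' @return a validated \linkS4class{SPAEventSet}.
#' @export
SPAEventSet <- function(times, location = "supragranular", lfpg = NULL,
                        mua = NULL, traceTimes = numeric()) {
    new("SPAEventSet", times = as.numeric(times), location = location,
        lfpg = if (is.null(lfpg)) matrix(numeric(), 0, 0) else lfpg,
        mua = if (is.null(mua)) matrix(numeric(), 0, 0) else mua,
        traceTimes = traceTimes)
}

#' Laminar layer map
#'
#' Default mapping of the 23 analysed laminar channels to cortical depth
#' compartments (1-8 supragranular, 9-13 granular, 14-23 infragranular),
#' with optional per-recording overrides that win over the defaults.
#'
#' @param overrides named character vector, e.g. \code{c("9" = "supragranular")}.
#' @return a \linkS4class{LayerMap}.
#' @export
layerMap <- function(overrides = character()) {
    if (length(overrides) && is.null(names(overrides)))
        stop("overrides must be named by channel number")
    new("LayerMap", overrides = overrides)
}

#' Layer of a laminar channel
#'
#' @param channel integer channel in 1..23 (vectorised).
#' @param map a \linkS4class{LayerMap}.
#' @return character vector of layer labels.
#' @examples
#' layerOf(5)   # supragranular
#' layerOf(10)  # granular
#' layerOf(10, layerMap(c("10" = "supragranular")))
#' @export
layerOf <- function(channel, map = layerMap()) {
    channel <- as.integer(channel)
    if (any(is.na(channel)) || any(channel < 1L | channel > 23L))
        stop("channel must be in 1..23")
    lab <- ifelse(channel <= 8L, "supragranular",
                  ifelse(channel <= 13L, "granular", "infragranular"))
    if (length(map@overrides)) {
        hit <- match(as.character(channel), names(map@overrides))
        lab[!is.na(hit)] <- map@overrides[hit[!is.na(hit)]]
    }
    lab
}

#' Segment pharmacological annotations into analysis epochs
#'
#' Each annotated bath block is trimmed by a guard interval at both ends
#' (rejecting transition periods between two states) and capped at a target
#' duration measured from the trimmed start. Excluded time is returned as
#' gaps so total annotated time is conserved:
#' epoch + overflow gaps + guards = annotated.
#'
#' @param annotations data.frame with columns \code{label} (control, APV,
#'   NBQX+APV, washout), \code{start}, \code{end} in s; ordered and
#'   non-overlapping.
#' @param guard_s guard trimmed from both ends of each block (s).
#' @param target_s epoch duration cap (s).
#' @return an \linkS4class{EpochSet}. Blocks shorter than the cap produce a
#'   short epoch (flagged with a message); blocks shorter than twice the
#'   guard produce none.
#' @examples
#' segmentEpochs(data.frame(label = "control", start = 0, end = 400))
#' @export
segmentEpochs <- function(annotations, guard_s = 30, target_s = 300) {
    assertNum(guard_s, "guard_s", lower = 0)
    assertNum(target_s, "target_s", lower = 0)
    stopifnot(all(c("label", "start", "end") %in% names(annotations)))
    ann <- annotations[order(annotations$start), , drop = FALSE]
    if (nrow(ann) > 1 && any(ann$start[-1] < ann$end[-nrow(ann)] - 1e-9))
        stop("annotations overlap")
    ep <- data.frame(label = character(), start = numeric(), end = numeric())
    gaps <- data.frame(start = numeric(), end = numeric(), why = character())
    for (i in seq_len(nrow(ann))) {
        a <- ann$start[i] + guard_s
        b <- ann$end[i] - guard_s
        if (b <= a) {
            gaps <- rbind(gaps, data.frame(start = ann$start[i],
                                           end = ann$end[i], why = "guard"))
            next
        }
        if (guard_s > 0) {
            gaps <- rbind(gaps,
                data.frame(start = c(ann$start[i], b), end = c(a, ann$end[i]),
                           why = "guard"))
        }
        end <- min(b, a + target_s)
        if (b - a < target_s)
            message(sprintf("short epoch '%s': %.1f s (< %.0f s target)",
                            ann$label[i], b - a, target_s))
        ep <- rbind(ep, data.frame(label = ann$label[i], start = a, end = end))
        if (end < b)
            gaps <- rbind(gaps, data.frame(start = end, end = b,
                                           why = "overflow"))
    }
    rownames(ep) <- rownames(gaps) <- NULL
    new("EpochSet", epochs = ep, gaps = gaps)
}

## ---- delimited-text readers / writers -------------------------------------
## Spike-event files: TSV with header (unit_id, time_s, channel), times as
## decimal seconds with >= 6 fractional digits; waveforms in a companion TSV
## keyed by unit_id, one row per sample.

#' Read / write a UnitSet as delimited text
#'
#' \code{readUnits} reads a tab-separated spike-event table (columns
#' \code{unit_id}, \code{time_s}, \code{channel}) plus an optional waveform
#' sidecar (columns \code{unit_id}, \code{sample}, \code{uV}).
#' \code{writeUnits} writes the same format with microsecond time precision.
#'
#' @param path spike table path (TSV).
#' @param waveformPath optional waveform sidecar path (TSV).
#' @param x a \linkS4class{UnitSet}.
#' @param duration,waveformRate optional overrides for \code{readUnits}.
#' @return \code{readUnits}: a \linkS4class{UnitSet}; \code{writeUnits}: the
#'   input, invisibly.
#' @export
readUnits <- function(path, waveformPath = NULL, duration = NULL,
                      waveformRate = 20000) {
    sp <- utils::read.delim(path, colClasses = c(unit_id = "character"))
    if (nrow(sp) == 0)
        return(UnitSet(data.frame(unit_id = character(), time_s = numeric()),
                       duration = if (is.null(duration)) 0 else duration))
    if ("channel" %in% names(sp) &&
        any(sp$channel < 1L | sp$channel > 23L))
        stop("unknown channel outside 1..23 in ", path)
    wf <- list()
    if (!is.null(waveformPath)) {
        w <- utils::read.delim(waveformPath,
                               colClasses = c(unit_id = "character"))
        w <- w[order(w$unit_id, w$sample), ]
        wf <- lapply(split(w$uV, w$unit_id), as.numeric)
    }
    UnitSet(sp, waveforms = wf, duration = duration,
            waveformRate = waveformRate)
}

#' @rdname readUnits
#' @export
writeUnits <- function(x, path, waveformPath = NULL) {
    sp <- x@spikes
    sp$time_s <- sprintf("%.6f", sp$time_s)
    if (length(x@channels))
        sp$channel <- x@channels[sp$unit_id]
    utils::write.table(sp, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(waveformPath) && length(x@waveforms)) {
        w <- do.call(rbind, lapply(names(x@waveforms), function(id)
            data.frame(unit_id = id,
                       sample = seq_along(x@waveforms[[id]]),
                       uV = sprintf("%.6f", x@waveforms[[id]]))))
        utils::write.table(w, waveformPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(x)
}

#' Read / write SPA events as delimited text
#'
#' Event table columns: \code{time_s}, \code{location}. Traces, when present,
#' go to sidecar TSVs with one row per event and one column per sample of the
#' common ms time base (column names are the times in ms).
#'
#' @param path event table path; \code{lfpgPath}/\code{muaPath} optional
#'   trace sidecars.
#' @param x a \linkS4class{SPAEventSet}.
#' @param lfpgPath,muaPath optional trace sidecar paths.
#' @return \code{readSpaEvents}: an \linkS4class{SPAEventSet};
#'   \code{writeSpaEvents}: the input, invisibly.
#' @export
readSpaEvents <- function(path, lfpgPath = NULL, muaPath = NULL) {
    ev <- utils::read.delim(path)
    readTr <- function(p) {
        if (is.null(p)) return(list(tr = NULL, t = numeric()))
        m <- as.matrix(utils::read.delim(p, check.names = FALSE))
        list(tr = unname(m), t = as.numeric(colnames(m)))
    }
    lf <- readTr(lfpgPath); mu <- readTr(muaPath)
    SPAEventSet(ev$time_s,
                location = if (nrow(ev)) ev$location[1] else "supragranular",
                lfpg = lf$tr, mua = mu$tr,
                traceTimes = if (length(lf$t)) lf$t else mu$t)
}

#' @rdname readSpaEvents
#' @export
writeSpaEvents <- function(x, path, lfpgPath = NULL, muaPath = NULL) {
    utils::write.table(
        data.frame(time_s = sprintf("%.6f", x@times), location = x@location),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeTr <- function(tr, p) {
        if (is.null(p) || is.null(tr)) return()
        colnames(tr) <- sprintf("%g", x@traceTimes)
        utils::write.table(format(tr, digits = 8), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    writeTr(lfpgTraces(x), lfpgPath)
    writeTr(muaTraces(x), muaPath)
    invisible(x)
}

#' Read / write an EM synapse record table
#'
#' One row per measured active zone: \code{patient_id}, \code{group}
#' (non-epileptic / epileptic), \code{region} (SPA / NoSPA), \code{synapse_id},
#' \code{az_length_um}, \code{perforated}, \code{target} (spine / dendrite /
#' unidentified), \code{multi_target}, \code{age}.
#'
#' @param path TSV path.
#' @param x synapse record data.frame.
#' @return \code{readSynapseTable}: data.frame with the columns above.
#' @export
readSynapseTable <- function(path) {
    x <- utils::read.delim(path, colClasses = c(patient_id = "character",
                                                synapse_id = "character"))
    x$perforated <- as.logical(x$perforated)
    x$multi_target <- as.logical(x$multi_target)
    validateSynapseTable(x)
    x
}

#' @rdname readSynapseTable
#' @export
writeSynapseTable <- function(x, path) {
    validateSynapseTable(x)
    x$az_length_um <- sprintf("%.6f", x$az_length_um)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(x)
}

validateSynapseTable <- function(x) {
    need <- c("patient_id", "group", "region", "synapse_id", "az_length_um",
              "perforated", "target", "multi_target", "age")
    if (!all(need %in% names(x)))
        stop("synapse table misses column(s): ",
             paste(setdiff(need, names(x)), collapse = ", "))
    if (any(as.numeric(x$az_length_um) <= 0))
        stop("active zone lengths must be positive")
    ## a synapse id seen on >1 record is by definition perforated
    nrec <- table(x$synapse_id)
    multi <- names(nrec)[nrec > 1L]
    if (length(multi) && !all(x$perforated[x$synapse_id %in% multi]))
        stop("synapse ids with multiple active zones must be flagged perforated")
    invisible(TRUE)
}
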