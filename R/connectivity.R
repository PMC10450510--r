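#' Spike-train crosscorrelogram of an ordered unit pair
#'
#' For each reference spike, target-minus-reference lags falling in
#' [-40, +40] ms are histogrammed at 1-ms bins (81 integer-centred bins;
#' bin c covers [c - 0.5, c + 0.5) ms). Positive lag means the target fires
#' after the reference. Baseline mean and SD are computed over the flank
#' bins with |lag| in [20, 40] ms, where a monosynaptic peak cannot lie.
#'
#' @param refTimes,targetTimes sorted spike times (s).
#' @param refId,targetId unit ids (must differ; a self-correlogram is not a
#'   pair).
#' @param bin_ms,window_ms binning.
#' @param baseline_ms c(lo, hi) absolute-lag band of the baseline flanks.
#' @return a \linkS4class{CrossCorrelogram}.
#' @export
crossCorrelogram <- function(refTimes, targetTimes, refId = "ref",
                             targetId = "target", bin_ms = 1, window_ms = 40,
                             baseline_ms = c(20, 40)) {
    if (identical(refId, targetId))
        stop("reference and target must be different units")
    stopifnot(length(refTimes) > 0, length(targetTimes) > 0)
    centers <- seq(-window_ms, window_ms, by = bin_ms)
    counts <- numeric(length(centers))
    w <- msToS(window_ms) + msToS(bin_ms) / 2
    idx <- findInterval(refTimes - w, targetTimes)
    for (i in seq_along(refTimes)) {
        j <- idx[i] + 1L
        while (j <= length(targetTimes) &&
               targetTimes[j] - refTimes[i] <= w) {
            lag <- sToMs(targetTimes[j] - refTimes[i])
            b <- round(lag / bin_ms) + window_ms / bin_ms + 1
            if (b >= 1 && b <= length(centers) &&
                lag < window_ms + bin_ms / 2 - 1e-12)
                counts[b] <- counts[b] + 1
            j <- j + 1L
        }
    }
    inBase <- abs(centers) >= baseline_ms[1] & abs(centers) <= baseline_ms[2]
    new("CrossCorrelogram", ref = refId, target = targetId, lags = centers,
        counts = counts, baselineMean = mean(counts[inBase]),
        baselineSD = stats::sd(counts[inBase]),
        nRef = length(refTimes))
}

#' Detect a putative synaptic connection from a crosscorrelogram
#'
#' The peak is the maximum bin on the causal side (positive lags, i.e. the
#' reference leading as the putative presynaptic cell; the zero-lag bin is
#' excluded as a common-input artifact). A connection is declared when the
#' peak count exceeds the baseline mean + \code{sdFactor} SDs AND the peak
#' bin holds at least \code{minCount} spikes (guarding against low-count
#' false positives): monosynaptic when the peak lag is 1-3 ms, polysynaptic
#' beyond 3 ms.
#'
#' @param ccg a \linkS4class{CrossCorrelogram}.
#' @param sdFactor baseline exceedance factor.
#' @param minCount minimum spike count in the peak bin.
#' @param mono_ms c(lo, hi) monosynaptic lag band (ms).
#' @return list: ref, target, verdict (none / monosynaptic / polysynaptic),
#'   peak_lag_ms, peak_count, threshold.
#' @export
detectConnection <- function(ccg, sdFactor = 2, minCount = 20,
                             mono_ms = c(1, 3)) {
    causal <- which(ccg@lags >= 1)
    pk <- causal[which.max(ccg@counts[causal])]
    peak <- ccg@counts[pk]
    lag <- ccg@lags[pk]
    thr <- ccg@baselineMean + sdFactor * ccg@baselineSD
    verdict <- "none"
    if (!is.na(thr) && peak > thr && peak >= minCount) {
        verdict <- if (lag >= mono_ms[1] && lag <= mono_ms[2]) "monosynaptic"
                   else "polysynaptic"
    }
    list(ref = ccg@ref, target = ccg@target, verdict = verdict,
         peak_lag_ms = lag, peak_count = peak, threshold = thr)
}

#' Scan all ordered unit pairs of a recording for connections
#'
#' Computes the crosscorrelogram and applies \code{\link{detectConnection}}
#' to every ordered pair of units with spikes (both orderings of each pair
#' are tested; the presynaptic candidate is always the reference).
#'
#' @param units a \linkS4class{UnitSet}.
#' @param ... passed to \code{\link{detectConnection}}.
#' @return data.frame: ref, target, verdict, peak_lag_ms, peak_count,
#'   threshold.
#' @export
detectConnections <- function(units, ...) {
    ids <- unitIds(units)
    ids <- ids[vapply(ids, function(i) length(spikeTimes(units, i)) > 0,
                      logical(1))]
    rows <- list()
    for (a in ids) for (b in ids) {
        if (a == b) next
        ccg <- crossCorrelogram(spikeTimes(units, a), spikeTimes(units, b),
                                a, b)
        d <- detectConnection(ccg, ...)
        rows[[length(rows) + 1L]] <- as.data.frame(d)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(ref = character(), target = character(),
                          verdict = character(), peak_lag_ms = numeric(),
                          peak_count = numeric(), threshold = numeric())
    rownames(out) <- NULL
    out
}

#' Contrast pre- vs postsynaptic members of detected pairs
#'
#' Mann-Whitney comparison of firing rate and burstiness between the
#' presynaptic (reference) and postsynaptic (target) members of the
#' connections that passed detection.
#'
#' @param candidates data.frame from \code{\link{detectConnections}},
#'   already filtered to \code{verdict != "none"}.
#' @param metrics data.frame with columns unit_id, rate_hz, burstiness
#'   (e.g. from \code{\link{activityMetrics}} on one epoch).
#' @return list with per-metric sublists (p, median_pre, median_post, q_pre,
#'   q_post) or \code{test = "insufficient"} when fewer than 3 pairs.
#' @export
prePostContrast <- function(candidates, metrics) {
    keep <- candidates$verdict != "none"
    cand <- candidates[keep, , drop = FALSE]
    if (nrow(cand) < 3)
        return(list(test = "insufficient", n_pairs = nrow(cand)))
    get <- function(ids, col)
        metrics[[col]][match(ids, metrics$unit_id)]
    one <- function(col) {
        pre <- get(cand$ref, col); post <- get(cand$target, col)
        ht <- suppressWarnings(stats::wilcox.test(pre, post))
        qs <- function(x) stats::quantile(x, c(.25, .5, .75), names = FALSE)
        list(p = ht$p.value, median_pre = stats::median(pre),
             median_post = stats::median(post),
             q_pre = qs(pre)[c(1, 3)], q_post = qs(post)[c(1, 3)])
    }
    list(test = "mann-whitney", n_pairs = nrow(cand),
         rate = one("rate_hz"), burstiness = one("burstiness"))
}
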