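#' Firing rate within an epoch
#'
#' Spike count inside the epoch divided by epoch duration.
#'
#' @param times spike times (s).
#' @param epoch c(start, end) s, or a one-row epoch data.frame.
#' @return rate in Hz.
#' @export
firingRate <- function(times, epoch) {
    if (is.data.frame(epoch)) epoch <- c(epoch$start[1], epoch$end[1])
    dur <- epoch[2] - epoch[1]
    if (dur <= 0) stop("epoch duration must be positive")
    sum(times >= epoch[1] & times < epoch[2]) / dur
}

#' Detect bursts (greedy maximal-window scan)
#'
#' A burst is a group of at least \code{min_spikes} spikes occurring within
#' a \code{window_ms} time window. The scan is greedy left-to-right: at
#' spike i, find the largest j with t(j) - t(i) <= window; if the group has
#' enough spikes, emit the burst [i, j] and continue at j + 1, otherwise
#' advance by one spike. A spike exactly at the window edge is inside.
#' Emitted bursts are disjoint and ordered.
#'
#' @param times sorted spike times (s).
#' @param window_ms burst window (ms).
#' @param min_spikes minimum spikes per burst.
#' @return data.frame: start_idx, end_idx (1-based into \code{times}),
#'   start_s, end_s, n_spikes.
#' @examples
#' detectBursts(c(0, 0.005, 0.010, 0.100))  # one burst of 3 spikes
#' @export
detectBursts <- function(times, window_ms = 20, min_spikes = 3) {
    w <- msToS(window_ms)
    n <- length(times)
    out <- list()
    i <- 1L
    while (i <= n) {
        j <- i
        while (j < n && times[j + 1L] - times[i] <= w + 1e-12) j <- j + 1L
        if (j - i + 1L >= min_spikes) {
            out[[length(out) + 1L]] <- data.frame(
                start_idx = i, end_idx = j, start_s = times[i],
                end_s = times[j], n_spikes = j - i + 1L)
            i <- j + 1L
        } else i <- i + 1L
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(start_idx = integer(), end_idx = integer(),
                    start_s = numeric(), end_s = numeric(),
                    n_spikes = integer())
}

#' Detect bursts by exhaustive window enumeration (reference implementation)
#'
#' Independent reference for \code{\link{detectBursts}}: enumerates every
#' qualifying window (i, j) with t(j) - t(i) <= window and >= min_spikes
#' spikes, keeps only windows that are maximal in extent at their start
#' spike, then selects disjoint windows left to right. Same semantics as the
#' greedy scan through a different code path; the two are equivalence-tested.
#'
#' @inheritParams detectBursts
#' @return same layout as \code{\link{detectBursts}}.
#' @export
detectBurstsExhaustive <- function(times, window_ms = 20, min_spikes = 3) {
    w <- msToS(window_ms)
    n <- length(times)
    cand <- list()
    for (i in seq_len(n)) {
        js <- which(times - times[i] <= w + 1e-12 & seq_len(n) >= i)
        j <- max(js)
        if (j - i + 1L >= min_spikes)
            cand[[length(cand) + 1L]] <- c(i, j)
    }
    out <- list()
    nextFree <- 1L
    for (c in cand) {
        if (c[1] >= nextFree) {
            out[[length(out) + 1L]] <- data.frame(
                start_idx = c[1], end_idx = c[2], start_s = times[c[1]],
                end_s = times[c[2]], n_spikes = c[2] - c[1] + 1L)
            nextFree <- c[2] + 1L
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(start_idx = integer(), end_idx = integer(),
                    start_s = numeric(), end_s = numeric(),
                    n_spikes = integer())
}

#' Burstiness index
#'
#' Fraction of spikes found within bursts, relative to the overall spike
#' count of the epoch; 0 when there are no spikes. Bursts are detected on
#' the whole train; a burst belongs to the epoch containing its first spike,
#' and only its spikes inside the epoch enter the numerator (so the index
#' stays in [0, 1]).
#'
#' @param times sorted spike times (s).
#' @param epoch optional c(start, end) restriction; whole train when NULL.
#' @param window_ms,min_spikes burst definition.
#' @return fraction in [0, 1].
#' @export
burstinessIndex <- function(times, epoch = NULL, window_ms = 20,
                            min_spikes = 3) {
    b <- detectBursts(times, window_ms, min_spikes)
    if (is.null(epoch)) {
        if (!length(times)) return(0)
        return(sum(b$n_spikes) / length(times))
    }
    if (is.data.frame(epoch)) epoch <- c(epoch$start[1], epoch$end[1])
    inEp <- times >= epoch[1] & times < epoch[2]
    if (!any(inEp)) return(0)
    b <- b[b$start_s >= epoch[1] & b$start_s < epoch[2], , drop = FALSE]
    nIn <- 0L
    for (k in seq_len(nrow(b)))
        nIn <- nIn + sum(inEp[b$start_idx[k]:b$end_idx[k]])
    nIn / sum(inEp)
}

#' Coefficient of variation of the inter-spike intervals
#'
#' Sample SD over mean of the ISIs within the epoch (n - 1 denominator).
#' Undefined (NA) with fewer than 3 spikes.
#'
#' @param times sorted spike times (s).
#' @param epoch optional c(start, end) restriction.
#' @return dimensionless CV, or NA.
#' @export
isiCv <- function(times, epoch = NULL) {
    if (!is.null(epoch)) {
        if (is.data.frame(epoch)) epoch <- c(epoch$start[1], epoch$end[1])
        times <- times[times >= epoch[1] & times < epoch[2]]
    }
    if (length(times) < 3) return(NA_real_)
    isi <- diff(times)
    stats::sd(isi) / mean(isi)
}

#' Per-unit, per-epoch activity metrics
#'
#' Firing rate, burstiness index and ISI CV for every unit and epoch.
#'
#' @param units a \linkS4class{UnitSet}.
#' @param epochSet an \linkS4class{EpochSet}.
#' @param window_ms,min_spikes burst definition.
#' @return data.frame: unit_id, label, rate_hz, burstiness, isi_cv.
#' @export
activityMetrics <- function(units, epochSet, window_ms = 20, min_spikes = 3) {
    ep <- epochs(epochSet)
    rows <- list()
    for (id in unitIds(units)) {
        t <- spikeTimes(units, id)
        for (k in seq_len(nrow(ep))) {
            win <- c(ep$start[k], ep$end[k])
            rows[[length(rows) + 1L]] <- data.frame(
                unit_id = id, label = ep$label[k],
                rate_hz = firingRate(t, win),
                burstiness = burstinessIndex(t, win, window_ms, min_spikes),
                isi_cv = isiCv(t, win))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
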