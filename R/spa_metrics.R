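#' SPA recurrence frequency within an epoch
#'
#' Number of SPA events falling in the epoch divided by the epoch duration.
#'
#' @param events an \linkS4class{SPAEventSet} or numeric event times (s).
#' @param epoch c(start, end) in s, or a one-row epoch data.frame.
#' @return frequency in Hz.
#' @examples
#' recurrenceFrequency(seq(0.5, 299.5, by = 1), c(0, 300))  # 1 Hz
#' @export
recurrenceFrequency <- function(events, epoch) {
    t <- if (is(events, "SPAEventSet")) eventTimes(events) else events
    if (is.data.frame(epoch)) epoch <- c(epoch$start[1], epoch$end[1])
    dur <- epoch[2] - epoch[1]
    if (dur <= 0) stop("epoch duration must be positive")
    sum(t >= epoch[1] & t < epoch[2]) / dur
}

#' Event-triggered average with baseline correction
#'
#' Pointwise mean across event traces minus the mean of the averaged trace
#' over the baseline window (-150 to -50 ms by default), so the baseline
#' segment of the output has zero mean.
#'
#' @param traces events x samples matrix.
#' @param times_ms trace time base (ms, event peak at 0).
#' @param baseline_ms c(lo, hi) baseline window in ms.
#' @return numeric averaged, baseline-corrected trace.
#' @export
eventTriggeredAverage <- function(traces, times_ms,
                                  baseline_ms = c(-150, -50)) {
    if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
    if (nrow(traces) < 1) stop("need at least one event trace")
    if (ncol(traces) != length(times_ms))
        stop("traces and time base differ in sample count")
    avg <- colMeans(traces)
    inBase <- times_ms >= baseline_ms[1] & times_ms < baseline_ms[2]
    if (!any(inBase)) stop("baseline window holds no samples")
    avg - mean(avg[inBase])
}

#' Peri-event amplitude of an averaged trace
#'
#' Maximum absolute value of the baseline-corrected average within the
#' peri-event window (+/- 50 ms by default; the measurement window mirrors
#' the peri-event window since no separate one is defined for amplitudes).
#'
#' @param avg baseline-corrected averaged trace.
#' @param times_ms trace time base (ms).
#' @param window_ms c(lo, hi) measurement window.
#' @return amplitude (same unit as the trace, microvolt in practice).
#' @export
spaAmplitude <- function(avg, times_ms, window_ms = c(-50, 50)) {
    inWin <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
    if (!any(inWin)) stop("measurement window holds no samples")
    max(abs(avg[inWin]))
}

#' Per-epoch SPA statistics
#'
#' Convenience wrapper computing event count, recurrence frequency and
#' baseline-corrected LFPg / MUA amplitudes of one SPA within one epoch.
#'
#' @param spa an \linkS4class{SPAEventSet} with traces.
#' @param epoch c(start, end) s, or one-row epoch data.frame with a
#'   \code{label}.
#' @return one-row data.frame: label, n_events, recurrence_hz, lfpg_uV,
#'   mua_uV.
#' @export
spaStats <- function(spa, epoch) {
    lab <- if (is.data.frame(epoch)) epoch$label[1] else NA_character_
    win <- if (is.data.frame(epoch)) c(epoch$start[1], epoch$end[1]) else epoch
    keep <- eventTimes(spa) >= win[1] & eventTimes(spa) < win[2]
    amp <- function(tr) {
        if (is.null(tr) || !any(keep)) return(NA_real_)
        spaAmplitude(eventTriggeredAverage(tr[keep, , drop = FALSE],
                                           traceTimes(spa)),
                     traceTimes(spa))
    }
    data.frame(label = lab, n_events = sum(keep),
               recurrence_hz = recurrenceFrequency(spa, win),
               lfpg_uV = amp(lfpgTraces(spa)), mua_uV = amp(muaTraces(spa)))
}

#' Compare an SPA property between two pharmacological epochs
#'
#' Paired design across SPAs (e.g. control vs APV recurrence frequency).
#' The per-SPA differences are gated through the D'Agostino-Pearson
#' normality test: paired t-test when normality holds (or when the sample is
#' too small for the normality test to be defined), Wilcoxon signed-rank
#' otherwise.
#'
#' @param control,treated numeric vectors, one value per SPA, paired by
#'   position.
#' @param alpha significance level for the normality gate.
#' @return list: \code{test} ("paired t" / "wilcoxon" / "insufficient"),
#'   \code{statistic}, \code{p}, \code{direction} ("decrease", "increase" or
#'   "none"), \code{n}.
#' @export
compareSpaAcrossEpochs <- function(control, treated, alpha = 0.05) {
    ok <- is.finite(control) & is.finite(treated)
    control <- control[ok]; treated <- treated[ok]
    n <- length(control)
    if (n < 3)
        return(list(test = "insufficient", statistic = NA_real_,
                    p = NA_real_, direction = "none", n = n))
    d <- treated - control
    if (all(d == 0))
        return(list(test = "degenerate", statistic = 0, p = 1,
                    direction = "none", n = n))
    normal <- if (n >= 8) {
        ap <- dagostinoPearson(d)
        is.na(ap$p) || ap$p >= alpha
    } else TRUE
    if (normal) {
        ht <- stats::t.test(treated, control, paired = TRUE)
        res <- list(test = "paired t", statistic = unname(ht$statistic),
                    p = ht$p.value)
    } else {
        ht <- suppressWarnings(stats::wilcox.test(treated, control,
                                                  paired = TRUE))
        res <- list(test = "wilcoxon", statistic = unname(ht$statistic),
                    p = ht$p.value)
    }
    res$direction <- if (res$p < alpha)
        if (mean(d) < 0) "decrease" else "increase" else "none"
    res$n <- n
    res
}
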