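#' Per-event baseline / peri-event spike counts
#'
#' For each SPA event (time zero = the event's LFPg peak), counts the unit's
#' spikes in the baseline window [-150, -50) ms and the peri-event window
#' [-50, +50) ms (half-open, time zero inside the peri window; the two
#' windows tile [-150, +50) exactly). Events whose windows are clipped by
#' the recording edges are dropped.
#'
#' @param times unit spike times (s).
#' @param events SPA event times (s) or an \linkS4class{SPAEventSet}.
#' @param duration_s recording duration used for edge clipping.
#' @param baseline_ms,peri_ms window bounds in ms relative to the event.
#' @return data.frame with one row per usable event: event_s, baseline,
#'   peri.
#' @export
windowCounts <- function(times, events, duration_s,
                         baseline_ms = c(-150, -50), peri_ms = c(-50, 50)) {
    ev <- if (is(events, "SPAEventSet")) eventTimes(events) else events
    lo <- msToS(min(baseline_ms, peri_ms))
    hi <- msToS(max(baseline_ms, peri_ms))
    ev <- ev[ev + lo >= 0 & ev + hi <= duration_s]
    if (!length(ev)) stop("no usable events inside the recording")
    cnt <- function(win)
        vapply(ev, function(e) sum(times >= e + msToS(win[1]) &
                                   times < e + msToS(win[2])), numeric(1))
    data.frame(event_s = ev, baseline = cnt(baseline_ms), peri = cnt(peri_ms))
}

#' Classify SPA-locked firing modulation of a unit
#'
#' Wilcoxon signed-rank test on per-event (baseline, peri) count pairs; the
#' unit is "increased" when the test is significant and the peri-event rate
#' is at least 1.5 times the baseline rate, "decreased" symmetrically at
#' 2/3, otherwise "unchanged". The two windows have equal length (100 ms) so
#' counts compare directly. A silent baseline with peri firing gives an
#' infinite relative change, reported as such and excluded from group means
#' downstream.
#'
#' @param counts data.frame from \code{\link{windowCounts}}.
#' @param alpha significance level.
#' @param minEvents fewer usable events than this yields "unchanged" with an
#'   insufficient-data flag.
#' @return list: class, p, change_pct (100 * peri / baseline), baseline_rate,
#'   peri_rate (Hz), n_events, flags.
#' @export
modulationClass <- function(counts, alpha = 0.05, minEvents = 10) {
    n <- nrow(counts)
    winLen <- 0.1                      # both windows are 100 ms
    bRate <- mean(counts$baseline) / winLen
    pRate <- mean(counts$peri) / winLen
    change <- if (bRate > 0) 100 * pRate / bRate
              else if (pRate > 0) Inf else NA_real_
    if (n < minEvents)
        return(list(class = "unchanged", p = NA_real_, change_pct = change,
                    baseline_rate = bRate, peri_rate = pRate, n_events = n,
                    flags = "insufficient events"))
    d <- counts$peri - counts$baseline
    p <- if (all(d == 0)) 1
         else suppressWarnings(stats::wilcox.test(counts$peri,
              counts$baseline, paired = TRUE))$p.value
    cls <- "unchanged"
    if (!is.na(p) && p < alpha) {
        if (pRate >= 1.5 * bRate) cls <- "increased"
        else if (pRate <= (2 / 3) * bRate) cls <- "decreased"
    }
    list(class = cls, p = p, change_pct = change, baseline_rate = bRate,
         peri_rate = pRate, n_events = n, flags = character())
}

## lagged design matrix: columns x[t-1] ... x[t-p]
lagMatrix <- function(x, p) {
    n <- length(x)
    sapply(seq_len(p), function(k) x[(p - k + 1):(n - k)])
}

#' Granger-causality screen: does unit activity predict upcoming SPA?
#'
#' Unit spikes and SPA events are binned into counts; a restricted linear
#' autoregression of the SPA series on its own past is compared against an
#' unrestricted one that adds the unit's past, at the model order (up to
#' \code{max_order}) minimising BIC of the unrestricted fit. BIC rather
#' than AIC: its stiffer penalty keeps the post-selection F-test on the
#' unit-lag block near its nominal level under the null while retaining
#' full power for real lagged dependence. The F-test measures whether the
#' unit's past improves the SPA prediction beyond the SPA's own history.
#'
#' @param times unit spike times (s).
#' @param events SPA event times (s) or an \linkS4class{SPAEventSet}.
#' @param duration_s recording duration (s); at least 60 s of data required.
#' @param bin_ms bin width (ms).
#' @param max_order maximum autoregressive order considered.
#' @param alpha pass level.
#' @return list: F, p, order, passes (p < alpha), n_bins.
#' @export
grangerUnitToSpa <- function(times, events, duration_s, bin_ms = 10,
                             max_order = 10, alpha = 0.05) {
    if (duration_s < 60) stop("need at least 60 s of recording")
    ev <- if (is(events, "SPAEventSet")) eventTimes(events) else events
    breaks <- seq(0, duration_s, by = msToS(bin_ms))
    x <- as.numeric(table(cut(times, breaks)))     # unit counts
    y <- as.numeric(table(cut(ev, breaks)))        # SPA counts
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant series: Granger model undefined")
    best <- NULL
    for (p in seq_len(max_order)) {
        yy <- y[(p + 1):length(y)]
        Yl <- lagMatrix(y, p); Xl <- lagMatrix(x, p)
        un <- stats::lm(yy ~ Yl + Xl)
        if (is.null(best) || stats::BIC(un) < best$bic)
            best <- list(bic = stats::BIC(un), p = p, yy = yy, Yl = Yl,
                         un = un)
    }
    re <- stats::lm(best$yy ~ best$Yl)
    ## F-test on the unit-lag block from residual sums of squares
    rssR <- sum(stats::residuals(re)^2)
    rssU <- sum(stats::residuals(best$un)^2)
    dfU <- length(best$yy) - (2 * best$p + 1)
    Fv <- ((rssR - rssU) / best$p) / (rssU / dfU)
    pv <- stats::pf(Fv, best$p, dfU, lower.tail = FALSE)
    list(F = Fv, p = pv, order = best$p, passes = !is.na(pv) && pv < alpha,
         n_bins = length(y))
}
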