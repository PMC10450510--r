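#' Classification rule set
#'
#' Thresholds of the waveform/autocorrelogram decision tree. The width cuts
#' are the published ones (principal cell if halfmax > 0.4 ms, interneuron if
#' < 0.2 ms, the closed band [0.2, 0.4] falling to unclassified); the
#' autocorrelogram qualifiers ("high peak", "fast exponential decay",
#' "sustained firing") are quantified here as exposed defaults since no
#' numeric values are published for them.
#'
#' @param pc_width_ms,in_width_ms halfmax width cuts (ms).
#' @param ib_peak_lo_ms,ib_peak_hi_ms lag band of the intrinsically bursting
#'   autocorrelogram peak.
#' @param acg_bin_ms,acg_window_ms autocorrelogram binning.
#' @param peak_prominence_factor a peak is "high" when it reaches this
#'   multiple of the 30-50 ms tail mean.
#' @param peak_min_count minimum spike-pair count in the peak bin for any
#'   peak to count as present at all; with sparse trains the tail mean is
#'   near zero and a ratio alone would promote single-pair noise bins.
#' @param decay_tau_max_ms "fast exponential decay": fitted time constant of
#'   the post-peak bins must not exceed this.
#' @param sustained_rate_min_hz "sustained firing" floor (Hz).
#' @return list of class \code{RuleSet}.
#' @export
ruleSet <- function(pc_width_ms = 0.4, in_width_ms = 0.2, ib_peak_lo_ms = 3,
                    ib_peak_hi_ms = 10, acg_bin_ms = 1, acg_window_ms = 50,
                    peak_prominence_factor = 2, peak_min_count = 10,
                    decay_tau_max_ms = 20, sustained_rate_min_hz = 0.5) {
    stopifnot(in_width_ms > 0, in_width_ms < pc_width_ms,
              ib_peak_lo_ms < ib_peak_hi_ms)
    r <- as.list(environment())
    class(r) <- "RuleSet"
    r
}

#' Action-potential width at half-maximal amplitude
#'
#' Width of the dominant waveform phase at half its absolute peak amplitude.
#' The dominant phase is the extremum of larger absolute value (so the
#' measure is invariant to sign flips and amplitude scaling); crossings are
#' located by linear interpolation between samples.
#'
#' @param waveform numeric mean waveform.
#' @param rate_hz waveform sampling rate.
#' @return width in ms.
#' @examples
#' t <- seq(-2, 2, by = 0.05)                    # ms at 20 kHz
#' w <- -exp(-t^2 / (2 * 0.2^2))                 # Gaussian, sd 0.2 ms
#' halfmaxWidth(w, 20000)                        # ~2*sqrt(2*log(2))*0.2
#' @export
halfmaxWidth <- function(waveform, rate_hz) {
    v <- as.numeric(waveform)
    if (max(v) - min(v) <= 0) stop("flat waveform has no halfmax width")
    i <- which.max(abs(v))
    s <- sign(v[i]); if (s == 0) s <- 1
    y <- s * v                       # dominant phase now positive
    peak <- y[i]
    half <- peak / 2
    ## walk left / right to the half crossings, linear interpolation
    l <- i
    while (l > 1 && y[l - 1] > half) l <- l - 1
    xl <- if (l == 1) 1 else (l - 1) + (half - y[l - 1]) / (y[l] - y[l - 1])
    r <- i
    nv <- length(y)
    while (r < nv && y[r + 1] > half) r <- r + 1
    xr <- if (r == nv) nv else r + (half - y[r]) / (y[r + 1] - y[r])
    (xr - xl) * 1000 / rate_hz
}

#' Spike-train autocorrelogram
#'
#' Counts of spike-pair lags in (0, window] at the given bin width; zero-lag
#' self pairs are excluded and, the histogram being symmetric, only positive
#' lags are stored.
#'
#' @param times sorted spike times (s).
#' @param bin_ms,window_ms binning (ms).
#' @return data.frame with \code{lag_ms} (bin centres) and \code{count};
#'   all-zero when fewer than 2 spikes.
#' @export
autocorrelogram <- function(times, bin_ms = 1, window_ms = 50) {
    nb <- ceiling(window_ms / bin_ms)
    out <- data.frame(lag_ms = (seq_len(nb) - 0.5) * bin_ms,
                      count = integer(nb))
    n <- length(times)
    if (n < 2) return(out)
    w <- msToS(window_ms)
    counts <- integer(nb)
    j <- 1L
    for (i in seq_len(n - 1L)) {
        k <- i + 1L
        while (k <= n && times[k] - times[i] <= w) {
            lag <- sToMs(times[k] - times[i])
            b <- min(nb, max(1L, ceiling(lag / bin_ms)))
            counts[b] <- counts[b] + 1L
            k <- k + 1L
        }
    }
    out$count <- counts
    out
}

## Exponential decay constant (ms) fitted to the bins after the ACG peak by
## log-linear regression; Inf when the decay is absent or too few bins.
acgDecayTau <- function(acg, peakIdx, span_ms = 20) {
    sel <- which(acg$lag_ms > acg$lag_ms[peakIdx] &
                 acg$lag_ms <= acg$lag_ms[peakIdx] + span_ms &
                 acg$count > 0)
    if (length(sel) < 4) return(Inf)
    fit <- stats::lm(log(acg$count[sel]) ~ acg$lag_ms[sel])
    slope <- stats::coef(fit)[2]
    if (is.na(slope) || slope >= 0) Inf else -1 / slope
}

#' Classify one unit from waveform width, autocorrelogram and rate
#'
#' Decision tree: (1) width above the principal-cell cut: IB-PC when the
#' autocorrelogram's global peak lies in the 3-10 ms band, is at least the
#' prominence factor times the 30-50 ms tail mean, and the post-peak decay
#' fits an exponential with a short time constant; RS-PC when the peak lag
#' exceeds 10 ms, or no prominent peak exists but firing is sustained;
#' otherwise UF-PC. (2) Width below the interneuron cut: IN (width is the
#' primary criterion; autocorrelogram shape is recorded as evidence only).
#' (3) The closed middle band: UC.
#'
#' @param width_ms halfmax width (ms).
#' @param acg autocorrelogram data.frame from \code{\link{autocorrelogram}},
#'   or NULL when unavailable.
#' @param mean_rate_hz mean firing rate (Hz).
#' @param rules a \code{\link{ruleSet}}.
#' @return list: \code{label} in RS-PC / IB-PC / UF-PC / IN / UC, and
#'   \code{evidence} (width_ms, acg_peak_ms, acg_peak_count, tail_mean,
#'   tau_ms, rate_hz, flags).
#' @export
classifyUnit <- function(width_ms, acg, mean_rate_hz, rules = ruleSet()) {
    ev <- list(width_ms = width_ms, acg_peak_ms = NA_real_,
               acg_peak_count = NA_real_, tail_mean = NA_real_,
               tau_ms = NA_real_, rate_hz = mean_rate_hz, flags = character())
    haveAcg <- !is.null(acg) && nrow(acg) > 0 && any(acg$count > 0)
    if (haveAcg) {
        pk <- which.max(acg$count)
        ev$acg_peak_ms <- acg$lag_ms[pk]
        ev$acg_peak_count <- acg$count[pk]
        tail <- acg$count[acg$lag_ms >= 30 & acg$lag_ms <= rules$acg_window_ms]
        ev$tail_mean <- if (length(tail)) mean(tail) else NA_real_
        ev$tau_ms <- acgDecayTau(acg, pk)
    }
    label <- if (width_ms > rules$pc_width_ms) {
        prominent <- haveAcg && !is.na(ev$tail_mean) &&
            ev$acg_peak_count >= rules$peak_min_count &&
            ev$acg_peak_count >= rules$peak_prominence_factor *
                max(ev$tail_mean, .Machine$double.eps)
        if (prominent && ev$acg_peak_ms >= rules$ib_peak_lo_ms &&
            ev$acg_peak_ms <= rules$ib_peak_hi_ms &&
            ev$tau_ms <= rules$decay_tau_max_ms) {
            "IB-PC"
        } else if ((prominent && ev$acg_peak_ms > rules$ib_peak_hi_ms) ||
                   (!prominent &&
                    mean_rate_hz >= rules$sustained_rate_min_hz)) {
            "RS-PC"
        } else "UF-PC"
    } else if (width_ms < rules$in_width_ms) {
        if (haveAcg && !is.na(ev$acg_peak_ms) && ev$acg_peak_ms <= 10)
            ev$flags <- c(ev$flags, "acg shape atypical for IN; width rules")
        "IN"
    } else {
        if (!haveAcg) ev$flags <- c(ev$flags, "insufficient evidence")
        "UC"
    }
    list(label = label, evidence = ev)
}

#' Classify every unit of a UnitSet
#'
#' Computes halfmax width from the stored mean waveform, the autocorrelogram
#' and mean rate from the spike train, then applies
#' \code{\link{classifyUnit}}.
#'
#' @param units a \linkS4class{UnitSet} with waveforms and spikes.
#' @param rules a \code{\link{ruleSet}}.
#' @return data.frame: unit_id, class, width_ms, acg_peak_ms, tau_ms,
#'   rate_hz.
#' @export
classifyUnits <- function(units, rules = ruleSet()) {
    ids <- unitIds(units)
    dur <- recordingDuration(units)
    rows <- lapply(ids, function(id) {
        wf <- waveformOf(units, id)
        t <- spikeTimes(units, id)
        width <- if (is.null(wf)) NA_real_
                 else halfmaxWidth(wf, units@waveformRate)
        acg <- if (length(t) >= 2)
            autocorrelogram(t, rules$acg_bin_ms, rules$acg_window_ms)
            else NULL
        rate <- if (dur > 0) length(t) / dur else 0
        cl <- classifyUnit(width, acg, rate, rules)
        data.frame(unit_id = id, class = cl$label, width_ms = width,
                   acg_peak_ms = cl$evidence$acg_peak_ms,
                   tau_ms = cl$evidence$tau_ms, rate_hz = rate)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
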