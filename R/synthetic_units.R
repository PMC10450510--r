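#' Simulation configuration
#'
#' Bundles every knob of the ground-truthed generator. Defaults emulate the
#' regime the analysis stack targets: unit firing around 0.2-3 Hz,
#' SPA events recurring near 1 Hz with peri-event rate modulation inside
#' +/- 50 ms, 300-s pharmacological epochs, intrinsically bursting cells
#' whose autocorrelogram peaks at 3-10 ms, and planted mono- (1-3 ms) and
#' polysynaptic (>3 ms) connections.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param epochDuration_s epoch length (s).
#' @param nUnits named integer vector of unit counts per true class
#'   (RS-PC, IB-PC, UF-PC, IN, UC).
#' @param rateRange named list of c(lo, hi) base-rate ranges (Hz) per class.
#' @param widthRange named list of c(lo, hi) waveform halfmax-width ranges
#'   (ms) per class; defaults keep classes margin-separated (PC > 0.45 ms,
#'   IN < 0.18 ms, UC inside 0.2-0.4 ms).
#' @param burstFraction,burstSize,intraBurstIsi_ms burst structure of IB-PC
#'   trains: fraction of events expanded into bursts, spikes per burst and
#'   intra-burst inter-spike interval (<= 6 ms; the default range keeps the
#'   autocorrelogram peak inside the 3-10 ms band that defines the class).
#' @param isiShape named Gamma ISI shape per class (1 = Poisson). Regular
#'   spiking cells get shape 3, a relative refractoriness that thins the
#'   short-lag autocorrelogram mass the way regular firing does in vivo.
#' @param epochEffect named multipliers applied to base rates per condition.
#' @param spaRate_hz,spaShape SPA renewal process: mean event rate and Gamma
#'   ISI shape (1 = Poisson, larger = more regular).
#' @param spaWindow_ms half-width of the peri-event modulation window.
#' @param lfpgAmp_uV,lfpgSigma_ms,lfpgNoise_uV LFPg transient amplitude,
#'   width and additive noise SD.
#' @param muaAmp_uV,muaBase_uV,muaNoise_uV MUA bump amplitude, rectified
#'   baseline level and noise SD.
#' @param traceWindow_ms trace window half-width (ms, 1-ms sampling).
#' @param waveformRate_hz,waveformSamples waveform sampling.
#' @param imageSize,cellRadius_px,cellRadiusSd_px,minSeparation_px,bgLevel,
#'   cellLevel,textureSd,textureScale_px,imageNoiseSd synthetic micrograph
#'   geometry: canvas (px), blob radius mean/SD, minimum centroid
#'   separation, bright background level, dark blob level, low-frequency
#'   texture SD and correlation scale, additive pixel noise SD.
#' @param synapsesPerPatient,nPatients,perfProb,spineProb,dendriteProb,
#'   multiTargetProb,lengthMeanlog,lengthSdlog,ageMean,ageSd EM table
#'   generator: records per patient and patients per group; per-group
#'   perforation probability; target-class probabilities; per
#'   group x perforation log-normal length parameters (um); per-group patient
#'   age distribution (years).
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      epochDuration_s = 300,
                      nUnits = c("RS-PC" = 12L, "IB-PC" = 12L, "UF-PC" = 12L,
                                 "IN" = 12L, "UC" = 12L),
                      rateRange = list("RS-PC" = c(1.5, 4), "IB-PC" = c(1, 3),
                                       "UF-PC" = c(0.1, 0.4), "IN" = c(2, 6),
                                       "UC" = c(0.5, 2)),
                      widthRange = list("RS-PC" = c(0.5, 0.7),
                                        "IB-PC" = c(0.5, 0.7),
                                        "UF-PC" = c(0.5, 0.7),
                                        "IN" = c(0.12, 0.17),
                                        "UC" = c(0.25, 0.35)),
                      burstFraction = 0.6, burstSize = c(3L, 5L),
                      intraBurstIsi_ms = c(4.2, 5.8),
                      isiShape = c("RS-PC" = 3, "IB-PC" = 1, "UF-PC" = 1,
                                   "IN" = 1, "UC" = 1),
                      epochEffect = c("control" = 1, "APV" = 1,
                                      "NBQX+APV" = 0.8, "washout" = 0.7),
                      spaRate_hz = 1, spaShape = 2, spaWindow_ms = 50,
                      lfpgAmp_uV = 22, lfpgSigma_ms = 12, lfpgNoise_uV = 2,
                      muaAmp_uV = 1.2, muaBase_uV = 0.3, muaNoise_uV = 0.1,
                      traceWindow_ms = 150,
                      waveformRate_hz = 20000, waveformSamples = 64L,
                      imageSize = c(512L, 512L), cellRadius_px = 8,
                      cellRadiusSd_px = 1.2, minSeparation_px = 26,
                      bgLevel = 0.85, cellLevel = 0.25, textureSd = 0.03,
                      textureScale_px = 12, imageNoiseSd = 0.01,
                      synapsesPerPatient = 75L, nPatients = c(3L, 3L),
                      perfProb = c("non-epileptic" = 0.204,
                                   "epileptic" = 0.288),
                      spineProb = c("non-epileptic" = 0.533,
                                    "epileptic" = 0.665),
                      dendriteProb = c("non-epileptic" = 0.388,
                                       "epileptic" = 0.302),
                      multiTargetProb = 0.03,
                      lengthMeanlog = c("non-perforated" = log(0.23),
                                        "perforated" = log(0.165)),
                      lengthSdlog = c("non-perforated" = 0.4,
                                      "perforated" = 0.35),
                      ageMean = c("non-epileptic" = 60, "epileptic" = 35),
                      ageSd = c("non-epileptic" = 12, "epileptic" = 12)) {
    cfg <- as.list(environment())
    stopifnot(all(cfg$nUnits >= 0), cfg$spaRate_hz >= 0, cfg$spaShape > 0,
              all(cfg$perfProb >= 0 & cfg$perfProb <= 1),
              all(unlist(cfg$intraBurstIsi_ms) <= 6))
    class(cfg) <- "SimConfig"
    cfg
}

## Gaussian-phase action-potential template with a given halfmax width.
## Main (negative) phase dominates; a smaller, slower positive after-wave
## makes the shape AP-like without moving the dominant extremum.
apTemplate <- function(width_ms, rate_hz, nSamples, amp_uV = 60) {
    dt <- 1000 / rate_hz                        # ms per sample
    t <- (seq_len(nSamples) - nSamples / 3) * dt
    sigma <- width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    main <- -exp(-t^2 / (2 * sigma^2))
    after <- 0.25 * exp(-(t - 3 * sigma)^2 / (2 * (2.5 * sigma)^2))
    amp_uV * (main + after)
}

#' Generate ground-truthed unit templates
#'
#' Draws per-unit true classes, waveform templates, base rates, burst
#' parameters and SPA modulation multipliers. Waveform halfmax widths are
#' margin-separated so the classes are unambiguous by construction: principal
#' cells > 0.45 ms, interneurons < 0.18 ms, unclassified inside (0.2, 0.4) ms;
#' IB-PC burst parameters put the autocorrelogram peak in 3-10 ms.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{units} (a \linkS4class{UnitSet} carrying waveforms
#'   and channels but no spikes yet) and \code{truth} (data.frame: unit_id,
#'   class, width_ms, rate_hz, burstFraction, burstSize, intraIsi_ms,
#'   spaMultiplier, channel).
#' @export
makeUnits <- function(cfg = simConfig()) {
    withSeed(cfg$seed, {
        classes <- rep(names(cfg$nUnits), cfg$nUnits)
        n <- length(classes)
        if (n == 0)
            return(list(units = UnitSet(data.frame(unit_id = character(),
                                                   time_s = numeric())),
                        truth = data.frame()))
        ids <- sprintf("u%02d", seq_len(n))
        width <- vapply(classes, function(cl)
            stats::runif(1, cfg$widthRange[[cl]][1], cfg$widthRange[[cl]][2]),
            numeric(1))
        rate <- vapply(classes, function(cl)
            stats::runif(1, cfg$rateRange[[cl]][1], cfg$rateRange[[cl]][2]),
            numeric(1))
        isIB <- classes == "IB-PC"
        truth <- data.frame(
            unit_id = ids, class = classes, width_ms = width, rate_hz = rate,
            burstFraction = ifelse(isIB, cfg$burstFraction, 0),
            burstSize = ifelse(isIB,
                sample(seq(cfg$burstSize[1], cfg$burstSize[2]), n,
                       replace = TRUE), 0L),
            intraIsi_ms = ifelse(isIB,
                stats::runif(n, cfg$intraBurstIsi_ms[1],
                             cfg$intraBurstIsi_ms[2]), 0),
            spaMultiplier = exp(stats::rnorm(n, 0, 0.3)),
            channel = sample(1:23, n, replace = TRUE),
            stringsAsFactors = FALSE)
        wf <- lapply(seq_len(n), function(i)
            apTemplate(width[i], cfg$waveformRate_hz, cfg$waveformSamples,
                       amp_uV = stats::runif(1, 40, 90)))
        names(wf) <- ids
        units <- UnitSet(data.frame(unit_id = character(), time_s = numeric()),
                         channels = structure(truth$channel, names = ids),
                         waveforms = wf, duration = 0,
                         waveformRate = cfg$waveformRate_hz)
        list(units = units, truth = truth)
    })
}

## Base event train on [start, end): Poisson (shape 1) or Gamma-renewal ISIs
## at the same mean rate. SPA modulation: multipliers < 1 thin spikes inside
## the peri-event windows; multipliers > 1 add Poisson spikes at the excess
## rate there, so the within-window rate is rate * mult either way.
renewalTrain <- function(rate, start, end, shape = 1, events = NULL,
                         mult = 1, window_s = 0.05) {
    if (rate <= 0 || end <= start) return(numeric())
    span <- end - start
    if (shape == 1) {
        t <- sort(stats::runif(stats::rpois(1, rate * span), start, end))
    } else {
        nMax <- ceiling(rate * span * 2 + 30)
        t <- start + cumsum(stats::rgamma(nMax, shape = shape,
                                          rate = shape * rate))
        t <- t[t < end]
    }
    if (!is.null(events) && length(events) && mult != 1) {
        ev <- events[events >= start - window_s & events <= end + window_s]
        if (length(ev)) {
            inWin <- vapply(t, function(ti)
                any(abs(ti - ev) <= window_s), logical(1))
            if (mult < 1) {
                drop <- inWin & stats::runif(length(t)) >= mult
                t <- t[!drop]
            } else {
                extra <- unlist(lapply(ev, function(e) {
                    lo <- max(start, e - window_s); hi <- min(end, e + window_s)
                    stats::runif(stats::rpois(1, rate * (mult - 1) * (hi - lo)),
                                 lo, hi)
                }))
                t <- sort(c(t, extra))
            }
        }
    }
    t
}

#' Simulate spike trains for a ground-truthed population
#'
#' Per unit and epoch, spikes are drawn as a Poisson process at the unit's
#' true rate (scaled by the condition's epoch effect); for bursty units a
#' fraction of events is expanded into bursts (>= 3 spikes at <= 6 ms
#' intra-burst intervals); inside +/- \code{spaWindow_ms} of each SPA event
#' the rate is multiplied by the unit's SPA modulation factor.
#'
#' @param truth data.frame from \code{\link{makeUnits}} (or same columns).
#' @param epochSet an \linkS4class{EpochSet}.
#' @param cfg a \code{\link{simConfig}}.
#' @param spa optional \linkS4class{SPAEventSet} whose events drive the
#'   peri-event modulation.
#' @param seed RNG seed; defaults to \code{cfg$seed + 1}.
#' @return a \linkS4class{UnitSet} with spike trains (waveforms not attached).
#' @export
simulateTrains <- function(truth, epochSet, cfg = simConfig(), spa = NULL,
                           seed = cfg$seed + 1L) {
    ep <- epochs(epochSet)
    stopifnot(nrow(ep) > 0)
    ev <- if (is.null(spa)) NULL else eventTimes(spa)
    withSeed(seed, {
        rows <- lapply(seq_len(nrow(truth)), function(i) {
            u <- truth[i, ]
            times <- numeric()
            for (k in seq_len(nrow(ep))) {
                eff <- cfg$epochEffect[[ep$label[k]]]
                if (is.null(eff) || is.na(eff)) eff <- 1
                shp <- if (!is.null(cfg$isiShape) && u$class %in%
                           names(cfg$isiShape)) cfg$isiShape[[u$class]] else 1
                base <- renewalTrain(u$rate_hz * eff, ep$start[k], ep$end[k],
                                     shape = shp, events = ev,
                                     mult = u$spaMultiplier,
                                     window_s = msToS(cfg$spaWindow_ms))
                if (u$burstFraction > 0 && length(base)) {
                    isB <- stats::runif(length(base)) < u$burstFraction
                    extra <- unlist(lapply(base[isB], function(t0) {
                        nb <- max(3L, u$burstSize) - 1L
                        t0 + cumsum(msToS(stats::runif(nb, 0.85, 1) *
                                          u$intraIsi_ms))
                    }))
                    base <- c(base, extra[extra < ep$end[k]])
                }
                times <- c(times, base)
            }
            times <- dedupeTimes(sort(times))
            if (length(times))
                data.frame(unit_id = u$unit_id, time_s = times)
            else NULL
        })
        sp <- do.call(rbind, rows)
        if (is.null(sp)) sp <- data.frame(unit_id = character(),
                                          time_s = numeric())
        UnitSet(sp,
                channels = structure(as.integer(truth$channel),
                                     names = truth$unit_id),
                duration = max(ep$end), waveformRate = cfg$waveformRate_hz)
    })
}

#' Plant a synaptic connection between two spike trains
#'
#' For each presynaptic spike, with probability \code{p} one postsynaptic
#' spike is added at the spike time plus \code{latency_ms} plus Gaussian
#' jitter; the postsynaptic train is re-sorted.
#'
#' @param pre,post numeric spike-time vectors (s).
#' @param latency_ms transmission latency, must be > 0 (1-3 ms mimics a
#'   monosynaptic, > 3 ms a polysynaptic link).
#' @param p transmission probability in [0, 1].
#' @param jitter_ms SD of the latency jitter.
#' @param seed RNG seed.
#' @return the augmented, sorted postsynaptic train.
#' @export
injectConnection <- function(pre, post, latency_ms, p, jitter_ms = 0.3,
                             seed = NULL) {
    assertNum(latency_ms, "latency_ms", lower = 1e-9)
    assertNum(p, "p", lower = 0, upper = 1)
    withSeed(seed, {
        fire <- stats::runif(length(pre)) < p
        add <- pre[fire] + msToS(latency_ms) +
            msToS(stats::rnorm(sum(fire), 0, jitter_ms))
        dedupeTimes(sort(c(post, add)))
    })
}
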