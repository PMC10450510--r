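#' Simulate a spontaneous population activity (SPA) event series with traces
#'
#' Event times follow a Gamma-renewal process at the configured mean rate
#' (shape 1 reduces to Poisson; the default shape 2 reflects the regularity
#' of recurring population bursts near 1 Hz). For each event a smooth LFPg
#' transient of configured amplitude plus additive Gaussian noise and a
#' rectified MUA trace elevated around the event peak are synthesized on a
#' common millisecond time base. Only events whose full trace window fits in
#' the recording are kept.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param duration_s recording span to fill with events (s).
#' @param location layer label carried by the SPA.
#' @param seed RNG seed; defaults to \code{cfg$seed + 2}.
#' @return an \linkS4class{SPAEventSet} with LFPg and MUA trace matrices.
#' @export
simulateSpa <- function(cfg = simConfig(), duration_s = 300,
                        location = "supragranular", seed = cfg$seed + 2L) {
    stopifnot(cfg$spaRate_hz > 0, duration_s > 0)
    withSeed(seed, {
        ## Gamma renewal: mean ISI = 1/rate with shape k => rate k*spaRate
        k <- cfg$spaShape
        n_max <- ceiling(cfg$spaRate_hz * duration_s * 2 + 50)
        isi <- stats::rgamma(n_max, shape = k, rate = k * cfg$spaRate_hz)
        times <- cumsum(isi)
        times <- times[times < duration_s]
        margin <- msToS(cfg$traceWindow_ms)
        times <- times[times >= margin & times <= duration_s - margin]
        tms <- seq(-cfg$traceWindow_ms, cfg$traceWindow_ms, by = 1)
        nT <- length(tms)
        nE <- length(times)
        bump <- exp(-tms^2 / (2 * cfg$lfpgSigma_ms^2))
        muaBump <- exp(-tms^2 / (2 * (cfg$lfpgSigma_ms * 0.8)^2))
        lf <- matrix(0, nE, nT)
        mu <- matrix(0, nE, nT)
        for (i in seq_len(nE)) {
            a <- cfg$lfpgAmp_uV * exp(stats::rnorm(1, 0, 0.1))
            lf[i, ] <- a * bump + stats::rnorm(nT, 0, cfg$lfpgNoise_uV)
            mu[i, ] <- cfg$muaBase_uV + cfg$muaAmp_uV * muaBump +
                abs(stats::rnorm(nT, 0, cfg$muaNoise_uV))
        }
        SPAEventSet(times, location = location, lfpg = lf, mua = mu,
                    traceTimes = tms)
    })
}
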