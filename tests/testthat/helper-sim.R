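## Shared simulation shorthand for the suite.

## Four 360-s pharmacological blocks; default guard 30 s leaves 4 x 300 s.
fourEpochAnnotations <- function() {
    data.frame(label = c("control", "APV", "NBQX+APV", "washout"),
               start = c(0, 360, 720, 1080), end = c(360, 720, 1080, 1440))
}

## Homogeneous Poisson train on [0, dur).
rpoisTrain <- function(rate, dur) {
    t <- sort(stats::runif(stats::rpois(1, rate * dur), 0, dur))
    t[c(TRUE, diff(t) > 2e-6)]
}

## Full synthetic recording: units + trains + classification inputs.
simRecording <- function(seed, cfg = simConfig(seed = seed)) {
    ep <- suppressMessages(segmentEpochs(fourEpochAnnotations()))
    mk <- makeUnits(cfg)
    tr <- simulateTrains(mk$truth, ep, cfg)
    units <- UnitSet(tr@spikes, channels = tr@channels,
                     waveforms = mk$units@waveforms,
                     duration = recordingDuration(tr),
                     waveformRate = cfg$waveformRate_hz)
    list(cfg = cfg, epochs = ep, truth = mk$truth, units = units)
}
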