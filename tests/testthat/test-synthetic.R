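test_that("generators are pure functions of config and seed", {
    cfg <- simConfig(seed = 42)
    expect_identical(makeUnits(cfg), makeUnits(cfg))
    ep <- suppressMessages(segmentEpochs(fourEpochAnnotations()))
    mk <- makeUnits(cfg)
    expect_identical(simulateTrains(mk$truth, ep, cfg),
                     simulateTrains(mk$truth, ep, cfg))
    expect_identical(simulateSpa(cfg, 60), simulateSpa(cfg, 60))
    expect_identical(renderCellsImage(20, cfg), renderCellsImage(20, cfg))
    expect_identical(simulateSynapseTable(cfg), simulateSynapseTable(cfg))
})

test_that("unit templates honour the class-separating width margins", {
    mk <- makeUnits(simConfig(seed = 7))
    w <- vapply(mk$truth$unit_id, function(id)
        halfmaxWidth(waveformOf(mk$units, id), 20000), numeric(1))
    cl <- mk$truth$class
    expect_true(all(w[cl %in% c("RS-PC", "IB-PC", "UF-PC")] > 0.45))
    expect_true(all(w[cl == "IN"] < 0.18))
    expect_true(all(w[cl == "UC"] > 0.2 & w[cl == "UC"] < 0.4))

    empty <- makeUnits(simConfig(seed = 1, nUnits = c("IN" = 0L)))
    expect_equal(nUnits(empty$units), 0L)
})

test_that("simulated train counts match the Poisson oracle", {
    ep <- new("EpochSet",
              epochs = data.frame(label = "control", start = 0, end = 300),
              gaps = data.frame(start = numeric(), end = numeric(),
                                why = character()))
    tru <- data.frame(unit_id = "x", class = "UC", rate_hz = 2,
                      burstFraction = 0, burstSize = 0L, intraIsi_ms = 0,
                      spaMultiplier = 1, channel = 5)
    cfg <- simConfig(seed = 1)
    counts <- vapply(1:200, function(s)
        length(spikeTimes(simulateTrains(tru, ep, cfg, seed = s), "x")),
        numeric(1))
    ## mean of 200 replicates of Poisson(600): SE = sqrt(600/200)
    expect_lt(abs(mean(counts) - 600), 3 * sqrt(600 / 200))
    expect_lt(abs(var(counts) - 600), 0.25 * 600)  # Poisson variance = mean

    silent <- tru; silent$rate_hz <- 0
    expect_length(spikeTimes(simulateTrains(silent, ep, cfg), "x"), 0)
})

test_that("burst injection saturates the burstiness index", {
    ep <- new("EpochSet",
              epochs = data.frame(label = "control", start = 0, end = 300),
              gaps = data.frame(start = numeric(), end = numeric(),
                                why = character()))
    tru <- data.frame(unit_id = "b", class = "IB-PC", rate_hz = 1,
                      burstFraction = 1, burstSize = 3L, intraIsi_ms = 5,
                      spaMultiplier = 1, channel = 5)
    tr <- simulateTrains(tru, ep, simConfig(seed = 2))
    expect_equal(burstinessIndex(spikeTimes(tr, "b")), 1.0, tolerance = 0.02)
})

test_that("connection injection follows the binomial oracle", {
    set.seed(11)
    pre <- rpoisTrain(5, 600)
    post <- rpoisTrain(1, 600)

    p1 <- injectConnection(pre, numeric(), latency_ms = 2, p = 1,
                           jitter_ms = 0, seed = 3)
    expect_equal(p1, pre + 0.002, tolerance = 1e-9)

    expect_identical(injectConnection(pre, post, 2, p = 0, seed = 3), post)
    expect_error(injectConnection(pre, post, latency_ms = 0, p = 0.5),
                 "latency_ms")

    added <- vapply(1:60, function(s)
        length(injectConnection(pre, post, 2, 0.3, 0.3, seed = s)) -
            length(post), numeric(1))
    n <- length(pre)
    expect_lt(abs(mean(added) - 0.3 * n),
              3 * sqrt(0.3 * 0.7 * n / 60))
})

test_that("SPA renewal counts and trace amplitudes match their oracles", {
    cfg <- simConfig(seed = 1, spaShape = 1)   # shape 1: Poisson counts
    n <- vapply(1:40, function(s)
        nEvents(simulateSpa(cfg, 300, seed = s)), numeric(1))
    ## ~0.3 s of edge margin per side is excluded from the event span
    expected <- 300 - 2 * 0.15
    expect_lt(abs(mean(n) - expected), 3 * sqrt(expected / 40))

    ## noise-free traces: measured event-triggered amplitude = configured
    quiet <- simConfig(seed = 5, lfpgNoise_uV = 0, muaNoise_uV = 0)
    spa <- simulateSpa(quiet, 120)
    avg <- eventTriggeredAverage(lfpgTraces(spa), traceTimes(spa))
    expect_equal(spaAmplitude(avg, traceTimes(spa)), quiet$lfpgAmp_uV,
                 tolerance = 0.05)
})

test_that("rendered micrographs have the requested blob geometry", {
    cfg <- simConfig(seed = 9)
    out <- renderCellsImage(0, cfg)
    expect_equal(nrow(out$centroids), 0L)
    expect_true(all(out$image > 0.5))   # background-only image stays bright

    out50 <- renderCellsImage(50, cfg)
    expect_equal(nrow(out50$centroids), 50L)
    d <- as.matrix(stats::dist(out50$centroids[, c("x", "y")]))
    diag(d) <- Inf
    expect_gte(min(d), cfg$minSeparation_px)

    expect_error(renderCellsImage(10000, cfg), "too many cells")
})

test_that("synthetic synapse tables satisfy the record invariants", {
    cfg <- simConfig(seed = 3)
    syn <- simulateSynapseTable(cfg)
    expect_true(all(syn$az_length_um > 0))
    nrec <- table(syn$synapse_id)
    multi <- names(nrec)[nrec > 1]
    expect_true(all(syn$perforated[syn$synapse_id %in% multi]))
    expect_true(all(table(syn$synapse_id[syn$perforated]) == 2))

    noperf <- simConfig(seed = 3,
                        perfProb = c("non-epileptic" = 0, "epileptic" = 0))
    expect_false(any(simulateSynapseTable(noperf)$perforated))
})

test_that("configured spine fraction is recovered at large n", {
    cfg <- simConfig(seed = 6, synapsesPerPatient = 1700L,
                     nPatients = c(3L, 3L),
                     spineProb = c("non-epileptic" = 0.665,
                                   "epileptic" = 0.665),
                     dendriteProb = c("non-epileptic" = 0.25,
                                      "epileptic" = 0.25))
    syn <- simulateSynapseTable(cfg)
    perSyn <- !duplicated(syn$synapse_id)
    frac <- mean(syn$target[perSyn] == "spine")
    n <- sum(perSyn)
    expect_lt(abs(frac - 0.665), 3 * sqrt(0.665 * 0.335 / n))
})
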