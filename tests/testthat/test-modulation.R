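test_that("window counts respect the half-open window conventions", {
    ## one spike 100 ms before the event: baseline only
    wc <- windowCounts(times = 0.9, events = 1.0, duration_s = 10)
    expect_equal(wc$baseline, 1)
    expect_equal(wc$peri, 0)

    ## a spike exactly at the event time is in the peri window
    wc <- windowCounts(times = 1.0, events = 1.0, duration_s = 10)
    expect_equal(wc$baseline, 0)
    expect_equal(wc$peri, 1)

    ## a spike exactly at -50 ms belongs to peri, not baseline (half-open)
    wc <- windowCounts(times = 0.95, events = 1.0, duration_s = 10)
    expect_equal(wc$baseline, 0)
    expect_equal(wc$peri, 1)

    wc <- windowCounts(numeric(), events = c(1, 2, 3), duration_s = 10)
    expect_true(all(wc$baseline == 0) && all(wc$peri == 0))

    ## events clipped by the recording edges are dropped
    wc <- windowCounts(1, events = c(0.1, 5), duration_s = 5.06)
    expect_equal(nrow(wc), 1L)
    expect_equal(wc$event_s, 5)
    expect_error(windowCounts(1, events = 0.05, duration_s = 0.08), "usable")
})

test_that("modulation classes apply both the test and the 50% gate", {
    same <- data.frame(event_s = 1:20, baseline = rep(2, 20),
                       peri = rep(2, 20))
    expect_equal(modulationClass(same)$class, "unchanged")

    few <- data.frame(event_s = 1:5, baseline = rep(0, 5), peri = rep(3, 5))
    r <- modulationClass(few)
    expect_equal(r$class, "unchanged")
    expect_equal(r$flags, "insufficient events")
    expect_true(is.infinite(r$change_pct))

    ## significant but only +30%: the 50% gate keeps it unchanged
    set.seed(30)
    base <- rpois(300, 10)
    up <- rpois(300, 13)
    r <- modulationClass(data.frame(event_s = 1:300, baseline = base,
                                    peri = up))
    expect_lt(r$p, 0.05)
    expect_equal(r$class, "unchanged")
})

test_that("planted peri-event modulation is detected with high power", {
    cfg <- simConfig(seed = 40)
    spa <- simulateSpa(cfg, 300)
    hits <- vapply(1:100, function(s) {
        tru <- data.frame(unit_id = "x", class = "UC", rate_hz = 2,
                          burstFraction = 0, burstSize = 0L, intraIsi_ms = 0,
                          spaMultiplier = 3, channel = 5)
        ep <- new("EpochSet",
                  epochs = data.frame(label = "control", start = 0,
                                      end = 300),
                  gaps = data.frame(start = numeric(), end = numeric(),
                                    why = character()))
        tr <- simulateTrains(tru, ep, cfg, spa = spa, seed = s)
        wc <- windowCounts(spikeTimes(tr, "x"), spa, 300)
        modulationClass(wc)$class == "increased"
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("null units are called unchanged at about the alpha level", {
    set.seed(41)
    calls <- replicate(300, {
        t <- rpoisTrain(2, 300)
        ev <- sort(runif(300, 1, 299))
        modulationClass(windowCounts(t, ev, 300))$class
    })
    ## significance AND the 50% gate: false calls stay below alpha
    expect_lte(mean(calls != "unchanged"), 0.05)
})

test_that("the Granger screen is calibrated and detects planted causality", {
    ## null: independent unit and SPA series
    set.seed(42)
    rej <- replicate(300, {
        t <- rpoisTrain(1.5, 120)
        ev <- rpoisTrain(1, 120)
        grangerUnitToSpa(t, ev, 120, max_order = 3)$p < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / 300) + 0.015)

    ## planted: SPA events are the unit's spikes delayed by 30 ms
    set.seed(43)
    power <- replicate(40, {
        u <- sort(runif(400, 1, 290))
        grangerUnitToSpa(u, sort(u + 0.03), 300)$p < 0.01
    })
    expect_gte(mean(power), 0.95)

    ## destroyed timing: an independently shuffled copy does not pass
    set.seed(44)
    passes <- replicate(40, {
        u <- sort(runif(300, 1, 290))
        grangerUnitToSpa(u, sort(runif(300, 1, 290)), 300)$passes
    })
    expect_lte(mean(passes), 0.15)

    expect_error(grangerUnitToSpa(rpoisTrain(1, 30), rpoisTrain(1, 30), 30),
                 "60 s")
    expect_error(grangerUnitToSpa(numeric(), rpoisTrain(1, 120), 120),
                 "constant")
})

test_that("the Granger F statistic matches an independent implementation", {
    skip_if_not_installed("lmtest")
    set.seed(45)
    t <- rpoisTrain(2, 200)
    ev <- sort(runif(180, 1, 199))
    mine <- grangerUnitToSpa(t, ev, 200, bin_ms = 10, max_order = 4)
    breaks <- seq(0, 200, by = 0.01)
    x <- as.numeric(table(cut(t, breaks)))
    y <- as.numeric(table(cut(ev, breaks)))
    ref <- lmtest::grangertest(x, y, order = mine$order)
    expect_equal(mine$F, ref$F[2], tolerance = 1e-8)
    expect_equal(mine$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
})
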