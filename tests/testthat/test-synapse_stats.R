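test_that("length summaries compute mean/SEM and interpolated quartiles", {
    rec <- data.frame(patient_id = "p", group = "g1", region = "SPA",
                      synapse_id = c("s1", "s2"), az_length_um = c(0.2, 0.3),
                      perforated = FALSE, target = "spine",
                      multi_target = FALSE, age = 50)
    s <- lengthSummary(rec, "group")
    expect_equal(s$mean, 0.25)
    expect_equal(s$sem, 0.05)
    expect_equal(s$median, 0.25)

    ## full factorial grouping emits one row per non-empty cell
    syn <- simulateSynapseTable(simConfig(seed = 80))
    s <- lengthSummary(syn, c("group", "region", "perforated"))
    expect_equal(nrow(s), 8L)
    expect_equal(sum(s$n), nrow(syn))

    ## generator oracle: large-n mean within 3 SEM of the configured truth
    cfg <- simConfig(seed = 81, synapsesPerPatient = 1700L,
                     perfProb = c("non-epileptic" = 0, "epileptic" = 0))
    big <- simulateSynapseTable(cfg)
    truthMean <- exp(cfg$lengthMeanlog[["non-perforated"]] +
                     cfg$lengthSdlog[["non-perforated"]]^2 / 2)
    s <- lengthSummary(big, "perforated")
    expect_lt(abs(s$mean - truthMean), 3 * s$sem)
})

test_that("proportions reproduce printed count arithmetic", {
    expect_equal(proportion(10, 219)$percent, 4.6)
    expect_equal(proportion(187, 281)$percent, 66.5)
    expect_equal(proportion(0, 50)$percent, 0)
    expect_error(proportion(1, 0), "denominator")

    ## logical-vector form
    syn <- simulateSynapseTable(simConfig(seed = 82))
    p <- proportion(syn$target == "spine", rep(TRUE, nrow(syn)))
    expect_equal(p$fraction, mean(syn$target == "spine"))
})

test_that("chi-square equals the textbook formula on random tables", {
    set.seed(83)
    for (i in 1:1000) {
        tab <- matrix(rpois(6, lambda = sample(5:60, 1)) + 1, 2, 3)
        ct <- contingencyTest(tab)
        ## independent brute-force: sum (O - E)^2 / E over all cells
        E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        stat <- sum((tab - E)^2 / E)
        expect_equal(ct$statistic, stat, tolerance = 1e-10)
        expect_equal(ct$p, pchisq(stat, df = 2, lower.tail = FALSE),
                     tolerance = 1e-10)
    }
})

test_that("the worked contingency examples reproduce printed p values", {
    ## postsynaptic target distribution, 2 x 3 counts
    target <- rbind(c(128, 93, 19), c(187, 85, 9))
    expect_equal(contingencyTest(target)$p, 0.0027, tolerance = 0.02)

    ## perforated ratio 2 x 2 reconstructed from the printed percentages
    perf <- rbind(c(round(0.204 * 240), 240 - round(0.204 * 240)),
                  c(round(0.288 * 281), 281 - round(0.288 * 281)))
    expect_equal(contingencyTest(perf)$p, 0.027, tolerance = 0.02)

    same <- rbind(c(30, 20, 10), c(30, 20, 10))
    expect_equal(contingencyTest(same)$p, 1)

    ## Yates and Fisher are available and ordered sensibly on a 2 x 2
    expect_gt(contingencyTest(perf, "yates")$p, contingencyTest(perf)$p)
    expect_true(is.na(contingencyTest(perf, "fisher")$statistic))
    expect_warning(contingencyTest(rbind(c(1, 0), c(0, 1)) * 1L), "Fisher")
})

test_that("Dunn z for two groups matches the Mann-Whitney normal z", {
    set.seed(84)
    x <- rnorm(15); y <- rnorm(18, 0.5)
    d <- dunnTest(c(x, y), rep(c("a", "b"), c(15, 18)))
    U <- unname(wilcox.test(x, y, exact = FALSE, correct = FALSE)$statistic)
    n1 <- 15; n2 <- 18; N <- n1 + n2
    zMW <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(abs(d$z), abs(zMW), tolerance = 1e-10)
})

test_that("group comparisons are gated, calibrated and powered", {
    ## identical constant groups: parametric route, no rejection
    r <- groupCompare(c(rnorm(20, 5, 1), rnorm(20, 5, 1)),
                      rep(c("a", "b"), each = 20))
    expect_true(r$test %in% c("t", "mann-whitney"))

    ## null calibration of the Kruskal-Wallis route over seeds
    set.seed(85)
    rej <- replicate(400, {
        v <- rlnorm(48)
        g <- rep(c("a", "b", "c", "d"), each = 12)
        groupCompare(v, g)$p < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 0.03)

    ## power: 0.05 um shift between groups at n = 120 vs 130
    set.seed(86)
    hits <- replicate(100, {
        v <- c(rlnorm(120, log(0.22), 0.4), rlnorm(130, log(0.27), 0.4))
        g <- rep(c("a", "b"), c(120, 130))
        groupCompare(v, g)$p < 0.05
    })
    expect_gte(mean(hits), 0.80)

    expect_warning(
        groupCompare(c(rnorm(10), rnorm(10, 2), 1),
                     rep(c("a", "b", "c"), c(10, 10, 1))),
        "excluding")
})

test_that("the age/epilepsy regression isolates the group effect", {
    syn <- simulateSynapseTable(simConfig(seed = 87))
    r <- ageEpilepsyRegression(syn)
    expect_equal(r$coefficients$term, c("(Intercept)", "age", "epileptic"))

    ## single group: status indicator is constant, rejected
    one <- data.frame(group = "epileptic", age = c(30, 35, 40, 45),
                      perf_fraction = c(0.2, 0.25, 0.3, 0.22))
    expect_error(ageEpilepsyRegression(one), "both patient groups")

    ## no age effect by construction: age p roughly uniform; group effect
    ## detected with decent power at a planted 15-point difference
    set.seed(88)
    nSim <- 150
    agep <- numeric(nSim); groupp <- numeric(nSim)
    for (i in seq_len(nSim)) {
        df <- data.frame(group = rep(c("non-epileptic", "epileptic"),
                                     each = 6),
                         age = c(rnorm(6, 60, 12), rnorm(6, 35, 12)))
        df$perf_fraction <- 0.2 + 0.15 * (df$group == "epileptic") +
            rnorm(12, 0, 0.05)
        r <- ageEpilepsyRegression(df)
        agep[i] <- r$coefficients$p[2]
        groupp[i] <- r$coefficients$p[3]
    }
    expect_lt(abs(mean(agep < 0.05) - 0.05), 0.06)
    expect_gte(mean(groupp < 0.05), 0.80)

    ## permuted group labels: group p becomes uniform
    set.seed(89)
    permp <- replicate(150, {
        df <- data.frame(group = sample(rep(c("non-epileptic", "epileptic"),
                                            each = 6)),
                         age = rnorm(12, 50, 15))
        df$perf_fraction <- 0.25 + rnorm(12, 0, 0.05)
        ageEpilepsyRegression(df)$coefficients$p[3]
    })
    expect_lt(abs(mean(permp < 0.05) - 0.05), 0.06)

    ## noise-free planted effect: essentially exact fit, p ~ 0
    df <- data.frame(group = rep(c("non-epileptic", "epileptic"), each = 4),
                     age = c(55, 60, 65, 70, 30, 35, 40, 45))
    df$perf_fraction <- 0.2 + 0.1 * (df$group == "epileptic") +
        1e-9 * rnorm(8)
    expect_lt(ageEpilepsyRegression(df)$coefficients$p[3], 1e-6)
})

test_that("every record lands in exactly one cell of a contingency table", {
    syn <- simulateSynapseTable(simConfig(seed = 90))
    tab <- table(syn$group, syn$target)
    expect_equal(sum(tab), nrow(syn))
    tab2 <- table(syn$group, syn$perforated)
    expect_equal(sum(tab2), nrow(syn))
})
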