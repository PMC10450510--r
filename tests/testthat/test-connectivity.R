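test_that("crosscorrelogram mass lands in the shifted bin", {
    ref <- seq(1, 100, by = 1)
    ccg <- crossCorrelogram(ref, ref + 0.002, "a", "b")
    expect_equal(sum(ccg@counts), 100)
    expect_equal(ccg@lags[which.max(ccg@counts)], 2)
    expect_error(crossCorrelogram(ref, ref, "a", "a"), "different units")
})

test_that("CCG(A,B) mirrored equals CCG(B,A) on random trains", {
    set.seed(50)
    for (i in 1:20) {
        a <- rpoisTrain(runif(1, 1, 4), 100)
        b <- rpoisTrain(runif(1, 1, 4), 100)
        ab <- crossCorrelogram(a, b, "a", "b")
        ba <- crossCorrelogram(b, a, "b", "a")
        expect_equal(ab@counts, rev(ba@counts))
    }
})

test_that("the detection rule needs both exceedance and absolute count", {
    flat <- new("CrossCorrelogram", ref = "a", target = "b",
                lags = seq(-40, 40), counts = rep(5, 81),
                baselineMean = 5, baselineSD = 0.5, nRef = 100L)
    expect_equal(detectConnection(flat)$verdict, "none")

    peaked <- flat
    peaked@counts[43] <- 15   # lag +2 ms, above mean + 2 SD but below 20
    expect_equal(detectConnection(peaked)$verdict, "none")
    peaked@counts[43] <- 25
    expect_equal(detectConnection(peaked)$verdict, "monosynaptic")
    expect_equal(detectConnection(peaked)$peak_lag_ms, 2)

    late <- flat; late@counts[47] <- 25    # lag +6 ms
    expect_equal(detectConnection(late)$verdict, "polysynaptic")

    ## the zero-lag bin is excluded from the peak search (common input)
    zero <- flat; zero@counts[41] <- 50
    expect_equal(detectConnection(zero)$verdict, "none")
})

test_that("planted connections are recovered with the right verdicts", {
    set.seed(51)
    pre <- rpoisTrain(5, 600)
    post <- rpoisTrain(1, 600)
    mono <- injectConnection(pre, post, 2, 0.3, 0.3, seed = 52)
    d <- detectConnection(crossCorrelogram(pre, mono, "pre", "post"))
    expect_equal(d$verdict, "monosynaptic")
    expect_equal(d$peak_lag_ms, 2)
    expect_gt(d$peak_count, 20)

    poly <- injectConnection(pre, post, 6, 0.3, 0.3, seed = 53)
    expect_equal(detectConnection(
        crossCorrelogram(pre, poly, "pre", "post"))$verdict, "polysynaptic")

    ## directionality: the reverse ordering must not fire at the same lag
    rev <- detectConnection(crossCorrelogram(mono, pre, "post", "pre"))
    expect_false(rev$verdict == "monosynaptic" && rev$peak_lag_ms == 2)
})

test_that("false-positive rate on independent pairs stays below 10%", {
    set.seed(54)
    fp <- replicate(500, {
        a <- rpoisTrain(runif(1, 1, 2), 300)
        b <- rpoisTrain(runif(1, 1, 2), 300)
        detectConnection(crossCorrelogram(a, b, "a", "b"))$verdict != "none"
    })
    expect_lt(mean(fp), 0.10)
})

test_that("detection sensitivity reaches 90% in the planted regime", {
    set.seed(55)
    hits <- replicate(50, {
        pre <- rpoisTrain(3, 600)
        post <- rpoisTrain(1.5, 600)
        post <- injectConnection(pre, post, 2, 0.2, 0.3)
        detectConnection(crossCorrelogram(pre, post, "a", "b"))$verdict ==
            "monosynaptic"
    })
    expect_gte(mean(hits), 0.90)
})

test_that("whole-recording pair scans report consistent directionality", {
    set.seed(56)
    sp <- list(u1 = rpoisTrain(4, 300), u2 = rpoisTrain(2, 300),
               u3 = rpoisTrain(1.5, 300))
    sp$u2 <- injectConnection(sp$u1, sp$u2, 2, 0.4, 0.3, seed = 57)
    units <- UnitSet(do.call(rbind, lapply(names(sp), function(id)
        data.frame(unit_id = id, time_s = sp[[id]]))), duration = 300)
    pairs <- detectConnections(units)
    expect_equal(nrow(pairs), 6L)
    hit <- pairs[pairs$verdict == "monosynaptic", ]
    expect_true(nrow(hit) >= 1)
    expect_true(any(hit$ref == "u1" & hit$target == "u2"))
    ## no pair is reported in both directions at the same positive lag
    for (i in seq_len(nrow(hit))) {
        mirror <- pairs$ref == hit$target[i] & pairs$target == hit$ref[i] &
            pairs$verdict != "none" & pairs$peak_lag_ms == hit$peak_lag_ms[i]
        expect_false(any(mirror))
    }
})

test_that("pre/post member contrasts detect planted rate differences", {
    empty <- data.frame(ref = "a", target = "b", verdict = "monosynaptic",
                        peak_lag_ms = 2, peak_count = 30, threshold = 10)
    expect_equal(prePostContrast(empty,
        data.frame(unit_id = c("a", "b"), rate_hz = c(1, 1),
                   burstiness = c(0, 0)))$test, "insufficient")

    set.seed(58)
    power <- replicate(40, {
        nPairs <- 15
        pre_ids <- sprintf("pre%d", 1:nPairs)
        post_ids <- sprintf("post%d", 1:nPairs)
        cand <- data.frame(ref = pre_ids, target = post_ids,
                           verdict = "monosynaptic", peak_lag_ms = 2,
                           peak_count = 30, threshold = 10)
        met <- data.frame(unit_id = c(pre_ids, post_ids),
                          rate_hz = c(rlnorm(nPairs, log(2), 0.3),
                                      rlnorm(nPairs, log(1), 0.3)),
                          burstiness = runif(2 * nPairs, 0, 0.5))
        prePostContrast(cand, met)$rate$p < 0.05
    })
    expect_gte(mean(power), 0.90)
})
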