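test_that("the ongoing window is exactly volumes 460-2304", {
    # 74000 frames over 8 planes = 9250 volumes; values encode the index
    tm <- TraceMatrix(matrix(rep(1:9250, each = 2), 2, byrow = FALSE) + 0.0,
                      volumeRate = 3.86)
    sel <- selectOngoingFrames(tm)
    expect_equal(ncol(sel), 1845)
    expect_equal(traceValues(sel)[1, ], 460:2304, ignore_attr = TRUE)
    # minimal input of exactly 2304 volumes
    tm2 <- TraceMatrix(matrix(1, 1, 2304), volumeRate = 3.86)
    expect_equal(ncol(selectOngoingFrames(tm2)), 1845)
    tm3 <- TraceMatrix(matrix(1, 1, 1000), volumeRate = 3.86)
    expect_error(selectOngoingFrames(tm3), "1000")
})

test_that("moving 8th-percentile baseline matches the brute-force oracle", {
    set.seed(3)
    x <- c(10, 10, 11, 10, 9, 10, 40, 10, 11, 10, 10, 9, 10)  # one spike
    tm <- TraceMatrix(matrix(x, 1), volumeRate = 1)
    pb <- dffPercentileBaseline(tm, window = 5, prob = 0.08)
    half <- 2   # floor(round(5 * 1) / 2)
    for (t in seq_along(x)) {
        win <- x[max(1, t - half):min(length(x), t + half)]
        expect_equal(pb$baseline[1, t], bruteQuantile(win, 0.08))
    }
    expect_equal(traceValues(pb$dff)[1, ],
                 (x - pb$baseline[1, ]) / pb$baseline[1, ],
                 ignore_attr = TRUE)
})

test_that("percentile dF/F is zero for constant traces and scale invariant", {
    tm <- TraceMatrix(matrix(7, 2, 50), volumeRate = 3.86)
    pb <- dffPercentileBaseline(tm)
    expect_equal(unique(as.numeric(pb$baseline)), 7)
    expect_equal(max(abs(traceValues(pb$dff))), 0)
    set.seed(9)
    v <- matrix(runif(200, 50, 150), 2)
    d1 <- dffPercentileBaseline(TraceMatrix(v, volumeRate = 3.86))
    d2 <- dffPercentileBaseline(TraceMatrix(v * 3, volumeRate = 3.86))
    expect_equal(traceValues(d1$dff), traceValues(d2$dff))
})

test_that("1 Hz resampling keeps constants, ramps and the sample count", {
    tm <- TraceMatrix(matrix(5, 1, 1845), volumeRate = 3.86)
    out <- resample1fps(tm)
    expect_equal(ncol(out), 478)
    expect_equal(unique(as.numeric(traceValues(out))), 5)
    expect_equal(volumeRate(out), 1)
    # linear ramp: value at second s is s * slope
    ramp <- matrix((0:999) / 3.86, 1)
    r1 <- resample1fps(ramp, volumeRate = 3.86)
    expect_equal(as.numeric(r1), 0:floor(999 / 3.86), tolerance = 1e-12)
    expect_error(resample1fps(matrix(1, 1, 10), volumeRate = 0.5), "> 1")
})

test_that("activity fractions count seconds above 4x baseline", {
    B <- matrix(10, 1, 450)
    F0 <- B
    m0 <- activityFraction(F0, B)
    expect_equal(m0$activeFraction, 0)
    expect_equal(m0$category, "inactive")
    F1 <- B; F1[1, 1:30] <- 50
    m1 <- activityFraction(F1, B)
    expect_equal(m1$activeFraction, 100 * 30 / 450, tolerance = 1e-9)
    expect_equal(m1$category, "inactive")
    F2 <- B; F2[1, 1:250] <- 50
    m2 <- activityFraction(F2, B)
    expect_equal(m2$activeFraction, 100 * 250 / 450, tolerance = 1e-9)
    expect_equal(m2$category, "highly_active")
    # threshold consistency: doubling both F and B changes nothing
    expect_equal(activityFraction(2 * F2, 2 * B)$activeFraction,
                 m2$activeFraction)
    expect_error(activityFraction(F2, B[, 1:10]), "differ")
})

test_that("region summaries and cumulative distributions are coherent", {
    m <- activityFraction(matrix(10, 4, 100), matrix(10, 4, 100))
    m$activeFraction <- c(5, 20, 60, 80)
    m$category <- c("inactive", "intermediate", "highly_active",
                    "highly_active")
    am <- regionActivitySummary(m, rep("TeO/thalamus", 4))
    rt <- regionTable(am)
    expect_equal(rt$pctHighlyActive, 50)
    expect_equal(rt$pctInactive, 25)
    cdf <- am@cdf[, "TeO/thalamus"]
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf[length(cdf)], 100, ignore_attr = TRUE)
    # all-silent cohort: curve at 100% from the first grid point
    m0 <- activityFraction(matrix(1, 3, 50), matrix(1, 3, 50))
    am0 <- regionActivitySummary(m0, rep("Habenula", 3))
    expect_equal(am0@cdf[1, "Habenula"], 100, ignore_attr = TRUE)
    expect_equal(regionTable(am0)$pctInactive, 100)
})

test_that("planted active fractions are recovered within 5 points per region", {
    cfg <- simulationConfig(nCells = 30, duration = 650,
                            evokedFractions = c(0, 0, 0),
                            activeFractions = seq(0, 0.8, by = 0.08),
                            seed = 5)
    sim <- simulateTraces(cfg)
    sp <- spontaneousActivity(sim$traces)
    truth <- cellData(sim$truth)
    rt <- regionTable(sp$metrics)
    for (reg in unique(truth$region)) {
        i <- truth$region == reg
        row <- rt[rt$region == reg, ]
        expect_lte(abs(row$pctHighlyActive -
                       100 * mean(truth$trueActiveFraction[i] > 0.5)), 5)
        expect_lte(abs(row$pctInactive -
                       100 * mean(truth$trueActiveFraction[i] < 0.1)), 5)
    }
    expect_lt(mean(abs(cellData(sp$metrics)$activeFraction -
                       100 * truth$trueActiveFraction)), 3)
})
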