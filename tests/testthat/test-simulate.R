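test_that("standard photic schedule places 5 one-minute stimuli at minutes 10..30", {
    sched <- makeStimulusSchedule(simulationConfig())
    expect_equal(onsets(sched), c(600, 900, 1200, 1500, 1800))
    expect_equal(offsets(sched), onsets(sched) + 60)
    # 2400 s recording holds the whole protocol
    expect_lt(max(offsets(sched)), 2400)
})

test_that("too-short recordings reject the schedule naming the first misfit", {
    cfg <- simulationConfig(duration = 700)
    expect_error(makeStimulusSchedule(cfg), "stimulus 2")
    expect_error(makeStimulusSchedule(simulationConfig(duration = 100)),
                 "stimulus 1")
})

test_that("a configuration without any variance source yields constant traces", {
    cfg <- simulationConfig(nCells = 4, duration = 30, spikeRate = 0,
                            noiseSd = 0, latentWeight = 0,
                            evokedFractions = c(0, 0, 0), seed = 3)
    sim <- simulateTraces(cfg)
    v <- traceValues(sim$traces)    # 4 cells in each of the 4 regions
    expect_equal(apply(v, 1, sd), rep(0, 16), ignore_attr = TRUE)
    expect_equal(v[, 1], cellData(sim$truth)$f0, ignore_attr = TRUE)
})

test_that("Poisson spiking is calibrated against the generator's own spike log", {
    cfg <- simulationConfig(nCells = 60, duration = 120, noiseSd = 0,
                            latentWeight = 0, evokedFractions = c(0, 0, 0),
                            seed = 8)
    sim <- simulateTraces(cfg)
    counts <- lengths(spikeTimes(sim$truth))
    expect_equal(counts, cellData(sim$truth)$spikeCount,
                 ignore_attr = TRUE)
    T <- floor(cfg@duration * cfg@volumeRate) / cfg@volumeRate
    expected <- cfg@spikeRate * T
    se <- sqrt(expected / length(counts))
    expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("identical config and seed reproduce traces bit for bit", {
    cfg <- simulationConfig(nCells = 8, duration = 40, seed = 11,
                            evokedFractions = c(0, 0, 0))
    s1 <- simulateTraces(cfg)
    s2 <- simulateTraces(cfg)
    expect_identical(traceValues(s1$traces), traceValues(s2$traces))
    expect_identical(cellData(s1$truth), cellData(s2$truth))
    s3 <- simulateTraces(simulationConfig(nCells = 8, duration = 40,
                                          seed = 12,
                                          evokedFractions = c(0, 0, 0)))
    expect_false(identical(traceValues(s1$traces), traceValues(s3$traces)))
})

test_that("cell placement respects region boxes and minimum separation", {
    cfg <- simulationConfig(nCells = 30, duration = 20, seed = 4,
                            evokedFractions = c(0, 0, 0))
    truth <- cellData(simulateTraces(cfg)$truth)
    geo <- cfg@regionGeometry
    for (i in seq_len(nrow(geo))) {
        sub <- truth[truth$region == geo$region[i], ]
        expect_true(all(sub$x >= geo$x0[i] & sub$x <= geo$x1[i]))
        expect_true(all(sub$y >= geo$y0[i] & sub$y <= geo$y1[i]))
        expect_true(all(sub$z >= geo$z0[i] & sub$z <= geo$z1[i]))
    }
    D <- as.matrix(dist(cbind(truth$x, truth$y, truth$z)))
    diag(D) <- Inf
    expect_gte(min(D), cfg@minSeparation)
})

test_that("response-class counts follow the configured fractions per region", {
    cfg <- simulationConfig(nCells = 40, duration = 2000,
                            evokedFractions = c(0.3, 0.1, 0.1), seed = 5)
    sched <- StimulusSchedule(c(300, 600, 900), c(360, 660, 960))
    truth <- cellData(simulateTraces(cfg, sched)$truth)
    for (reg in unique(truth$region)) {
        cls <- truth$responseClass[truth$region == reg]
        expect_equal(sum(cls == "on_activated"), 12)
        expect_equal(sum(cls == "off_activated"), 4)
        expect_equal(sum(cls == "inhibited"), 4)
    }
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(noiseSd = -0.1), "amplitudes")
    expect_error(simulationConfig(f0Range = c(0, 10)), "f0Range")
    expect_error(simulationConfig(evokedFractions = c(0.6, 0.3, 0.3)),
                 "fractions")
})

test_that("planted active fractions are realized on the burst grid", {
    cfg <- simulationConfig(nCells = 5, duration = 200,
                            evokedFractions = c(0, 0, 0),
                            activeFractions = c(0, 0.2, 0.4, 0.6, 0.8),
                            seed = 6)
    truth <- cellData(simulateTraces(cfg)$truth)
    expect_equal(sort(unique(truth$trueActiveFraction)),
                 c(0, 0.2, 0.4, 0.6, 0.8))
})

test_that("analytic pairwise correlation decays with distance from lambda^2 share", {
    cfg <- tinyConfig()
    sim <- simulateTraces(cfg)
    r <- analyticCorrelation(sim$truth, c(0, 20, 60))
    expect_true(all(diff(r) < 0))
    expect_true(all(r >= 0 & r <= 1))
    # closed form at d = 0: lambda^2 / (A^2 Var(c) + lambda^2 + sigma^2)
    a <- exp(-1 / (cfg@volumeRate * cfg@kernelDecayTau))
    varc <- cfg@spikeRate / cfg@volumeRate / (1 - a^2)
    r0 <- cfg@latentWeight^2 /
        (cfg@transientAmplitude^2 * varc + cfg@latentWeight^2 + cfg@noiseSd^2)
    expect_equal(r[1], r0)
    tp <- truePairCorrelations(sim$truth, 60)
    expect_true(all(tp$distance <= 60))
    expect_equal(tp$r, analyticCorrelation(sim$truth, tp$distance))
})
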