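# Direct arithmetic checks use hand-built TraceMatrix objects; recovery
# checks use the generator with the compact 5-stimulus protocol.

test_that("trial averaging is the pointwise mean across aligned windows", {
    rate <- 2
    nT <- 400
    vals <- matrix(10, 2, nT)
    sched <- StimulusSchedule(c(50, 100, 150), c(60, 110, 160))
    # cell 1: identical bump every trial; average equals one trial
    for (on in onsets(sched))
        vals[1, (on * rate + 1):(on * rate + 10)] <- 14
    # cell 2: one timepoint (5 volumes after onset) takes values 1..3
    for (k in 1:3) vals[2, onsets(sched)[k] * rate + 5] <- k
    tm <- TraceMatrix(vals, volumeRate = rate)
    tr <- trialAverage(tm, sched, pre = 5, post = 10)
    expect_equal(tr$nTrials, 3)
    oneTrial <- vals[1, (50 * rate - 9):(50 * rate + 40)]
    expect_equal(tr$avg[1, ], oneTrial, ignore_attr = TRUE)
    expect_equal(tr$avg[2, tr$time == 2], 2, ignore_attr = TRUE)  # 1,2,3 -> 2
    expect_error(trialAverage(tm, StimulusSchedule(2, 12), pre = 5),
                 "trial 1")
})

test_that("dF/F against the 5-s pre-baseline is exact and scale invariant", {
    trial <- list(avg = matrix(c(9, 10, 11, 15, 15), 1), nTrials = 5,
                  time = c(-3, -2, -1, 0, 1), stimDuration = 1,
                  preFrames = 3)
    d <- dffFromPreBaseline(trial)
    expect_equal(d$dff[1, 4], 0.5)
    expect_equal(d$baselineSd[1], sd(c(-0.1, 0, 0.1)))
    trialC <- trial
    trialC$avg <- trial$avg * 7
    expect_equal(dffFromPreBaseline(trialC)$dff, d$dff)
    # constant trial: dF/F identically zero with zero baseline SD
    flat <- list(avg = matrix(5, 1, 5), time = c(-2, -1, 0, 1, 2),
                 nTrials = 5, stimDuration = 1, preFrames = 2)
    df <- dffFromPreBaseline(flat)
    expect_equal(as.numeric(df$dff), rep(0, 5))
    expect_equal(df$baselineSd, 0)
    bad <- flat; bad$avg <- matrix(c(-5, -5, 1, 1, 1), 1)
    expect_error(dffFromPreBaseline(bad), "non-positive")
})

test_that("the 2-SD rule classifies activated, inhibited and none", {
    mk <- function(amp) list(
        dff = cbind(matrix(0, 3, 4), matrix(amp, 3, 20)),
        time = seq(-2, 9.5, by = 0.5), baselineSd = rep(0.1, 3),
        stimDuration = 2, nTrials = 5)
    trial <- mk(c(0.5, -0.5, 0.15))
    cl <- classifyResponse(trial, "ON", window = 6)
    expect_equal(cl$class, c("activated", "inhibited", "none"))
    expect_equal(cl$amplitude, c(0.5, -0.5, 0.15))
    # degenerate zero-SD input is classified by sign and flagged
    trial$baselineSd <- rep(0, 3)
    cl0 <- classifyResponse(trial, "ON", window = 6)
    expect_equal(cl0$class, c("activated", "inhibited", "activated"))
    expect_true(all(cl0$flagged))
})

test_that("classification never calls a cell both activated and inhibited", {
    set.seed(42)
    for (rep in 1:20) {
        trial <- list(dff = matrix(rnorm(5 * 30, sd = 0.3), 5),
                      time = seq(-2.5, 12, by = 0.5)[1:30],
                      baselineSd = runif(5, 0, 0.2), stimDuration = 3,
                      nTrials = 5)
        on <- classifyResponse(trial, "ON", window = 5)
        off <- classifyResponse(trial, "OFF", window = 5)
        expect_false(any(on$class == "activated" & on$class == "inhibited"))
        expect_true(all(on$class %in% c("activated", "inhibited", "none")))
        expect_true(all(off$class %in% c("activated", "inhibited", "none")))
    }
})

test_that("classification is invariant to rescaling the raw traces", {
    cfg <- simulationConfig(nCells = 15, duration = 300, seed = 17)
    sim <- simulateTraces(cfg, shortSchedule())
    ev1 <- evokedResponses(sim$traces, shortSchedule())
    scaled <- TraceMatrix(traceValues(sim$traces) * 4.2,
                          volumeRate = volumeRate(sim$traces),
                          cells = cellData(sim$traces))
    ev2 <- evokedResponses(scaled, shortSchedule())
    expect_equal(cellData(ev1)$onClass, cellData(ev2)$onClass)
    expect_equal(cellData(ev1)$offClass, cellData(ev2)$offClass)
    expect_equal(cellData(ev1)$onAmplitude, cellData(ev2)$onAmplitude)
})

test_that("region summary computes percentages over assigned cells", {
    cells <- S4Vectors::DataFrame(
        id = 1:12,
        region = c(rep("TeO/thalamus", 10), "unassigned", "unassigned"),
        onAmplitude = c(rep(0.5, 3), rep(0, 7), 0, 0),
        onClass = c(rep("activated", 3), rep("none", 7), "none", "none"),
        offAmplitude = 0, offClass = "none", baselineSd = 0.1,
        flagged = FALSE)
    ev <- new("EvokedResult", cells = cells, regions = data.frame(),
              nTrials = 5L, avgTime = numeric(), avgDff = matrix(0, 0, 0),
              windows = list())
    rs <- regionSummary(ev)
    on <- rs[rs$condition == "ON", ]
    expect_equal(on$pctActivated, 30)
    expect_equal(on$pctInhibited, 0)
    expect_equal(on$n, 10)
    expect_equal(attr(rs, "nUnassigned"), 2)
    expect_true(all(rs$pctActivated + rs$pctInhibited <= 100))
})

test_that("planted responder fractions are recovered within 5 points", {
    cfg <- simulationConfig(nCells = 50, duration = 300,
                            evokedFractions = c(0.3, 0.1, 0.1), seed = 23)
    sim <- simulateTraces(cfg, shortSchedule())
    ev <- evokedResponses(sim$traces, shortSchedule())
    truth <- cellData(sim$truth)
    cls <- cellData(ev)
    onTrue <- truth$responseClass == "on_activated"
    inhTrue <- truth$responseClass == "inhibited"
    expect_gte(mean(cls$onClass[onTrue] == "activated"), 0.9)  # sensitivity
    expect_gte(mean(cls$onClass[!onTrue] != "activated"), 0.9) # specificity
    rs <- regionTable(ev)
    for (reg in unique(truth$region)) {
        i <- truth$region == reg
        row <- rs[rs$region == reg & rs$condition == "ON", ]
        expect_lte(abs(row$pctActivated - 100 * mean(onTrue[i])), 5)
        expect_lte(abs(row$pctInhibited - 100 * mean(inhTrue[i])), 5)
    }
})
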