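segConfig <- function(..., seed = 21) {
    simulationConfig(nCells = 12, duration = 30, planeCount = 2,
                     frameSize = c(192L, 160L), evokedFractions = c(0, 0, 0),
                     noiseSd = 0.05, nucleusRadius = 4, seed = seed, ...)
}

test_that("a single constant-trace cell renders exactly as its disc template", {
    cfg <- simulationConfig(nCells = c(1L, 0L, 0L, 0L), duration = 5,
                            planeCount = 1L, frameSize = c(64L, 64L),
                            spikeRate = 0, noiseSd = 0, latentWeight = 0,
                            evokedFractions = c(0, 0, 0), seed = 2)
    sim <- simulateTraces(cfg)
    rn <- renderMovie(sim$traces, sim$truth, cfg)
    truth <- cellData(sim$truth)
    img <- movieFrame(rn$movie, 1, 1)
    f0 <- truth$f0[1]
    row <- round(truth$y[1]) + 1; col <- round(truth$x[1]) + 1
    expect_equal(img[row, col], f0)
    expect_equal(img[row, col + 3], f0)       # inside radius-4 disc
    expect_equal(img[row, col + 5], 0)        # outside
    expect_equal(sum(img > 0), nrow(zfBrainActivity:::.discOffsets(4)))
})

test_that("zero-noise render/extract round trip recovers every trace", {
    cfg <- segConfig()
    sim <- simulateTraces(cfg)
    rn <- renderMovie(sim$traces, sim$truth, cfg)
    truth <- cellData(sim$truth)
    rois <- ROISet(S4Vectors::DataFrame(
        id = truth$id, x = truth$x, y = truth$y, plane = truth$plane,
        z = truth$z, radius = cfg@nucleusRadius, region = truth$region))
    ex <- extractTraces(rn$movie, rois)
    rel <- abs(traceValues(ex) - traceValues(sim$traces)) /
        traceValues(sim$traces)
    expect_lt(max(rel), 0.01)
    for (i in seq_len(nrow(ex)))
        expect_gt(cor(traceValues(ex)[i, ], traceValues(sim$traces)[i, ]),
                  0.99)
})

test_that("cells outside the frame are rejected at render time", {
    cfg <- simulationConfig(nCells = c(1L, 0L, 0L, 0L), duration = 5,
                            planeCount = 1L, frameSize = c(64L, 64L),
                            evokedFractions = c(0, 0, 0), seed = 2)
    sim <- simulateTraces(cfg)
    sim$truth@cells$x[1] <- 500
    expect_error(renderMovie(sim$traces, sim$truth, cfg), "outside")
})

test_that("blank images yield no detections and non-finite images error", {
    expect_equal(nrow(cellData(detectNuclei(matrix(3, 80, 80)))), 0)
    expect_error(detectNuclei(matrix(c(1, NA), 10, 10)), "finite")
    expect_error(detectNuclei(matrix(1, 10, 10), radii = integer()),
                 "radii")
})

test_that("nuclei are detected with sub-pixel-scale centroid error", {
    cfg <- segConfig()
    sim <- simulateTraces(cfg)
    rn <- renderMovie(sim$traces, sim$truth, cfg)
    truth <- cellData(sim$truth)
    for (p in 1:2) {
        det <- detectNuclei(meanImage(rn$movie, p), radii = 3:6, plane = p)
        m <- matchDetections(det, truth[truth$plane == p, ])
        expect_equal(m$tp, sum(truth$plane == p))
        expect_equal(m$fp, 0)
        expect_lte(max(m$err), 1)
    }
})

test_that("two nuclei beyond the suppression distance give two detections", {
    img <- matrix(0, 64, 64)
    off <- zfBrainActivity:::.discOffsets(4)
    for (ctr in list(c(20, 20), c(20, 40)))
        img[cbind(ctr[1] + off$dr, ctr[2] + off$dc)] <- 100
    det <- detectNuclei(img, radii = 3:5, minSeparation = 5)
    expect_equal(nrow(cellData(det)), 2)
})

test_that("detection is equivariant under integer image translation", {
    cfg <- segConfig(seed = 31)
    sim <- simulateTraces(cfg)
    rn <- renderMovie(sim$traces, sim$truth, cfg)
    img <- meanImage(rn$movie, 1)
    d0 <- cellData(detectNuclei(img, radii = 3:6))
    sh <- img[, c(4:ncol(img), rep(ncol(img), 3))]  # shift left by 3 cols
    d1 <- cellData(detectNuclei(sh, radii = 3:6))
    interior <- d0$x > 10 & d0$x < ncol(img) - 10
    shifted <- sort(d0$x[interior] - 3)
    expect_true(all(vapply(shifted, function(x)
        any(abs(d1$x - x) < 1e-9), logical(1))))
})

test_that("extraction is linear in intensity and constant on uniform images", {
    frames <- array(7.5, dim = c(1, 4, 32, 32))
    mv <- Movie(frames, volumeRate = 2)
    roi <- ROISet(S4Vectors::DataFrame(id = 1L, x = 15, y = 15, plane = 1L,
                                       z = 0, radius = 3,
                                       region = "unassigned"))
    tr <- extractTraces(mv, roi)
    expect_equal(as.numeric(traceValues(tr)), rep(7.5, 4))
    mv2 <- Movie(frames * 3, volumeRate = 2)
    expect_equal(traceValues(extractTraces(mv2, roi)),
                 traceValues(tr) * 3)
    roiOut <- ROISet(S4Vectors::DataFrame(id = 1L, x = 200, y = 200,
                                          plane = 1L, z = 0, radius = 3,
                                          region = "unassigned"))
    expect_error(extractTraces(mv, roiOut), "outside")
})

test_that("clipped footprints are flagged, not fatal", {
    frames <- array(2, dim = c(1, 3, 32, 32))
    mv <- Movie(frames, volumeRate = 2)
    roi <- ROISet(S4Vectors::DataFrame(id = 1L, x = 1, y = 15, plane = 1L,
                                       z = 0, radius = 4,
                                       region = "unassigned"))
    tr <- extractTraces(mv, roi)
    expect_true(cellData(tr)$clipped[1])
    expect_equal(as.numeric(traceValues(tr)), rep(2, 3))
})

test_that("region assignment reproduces generator labels and counts", {
    cfg <- segConfig()
    sim <- simulateTraces(cfg)
    rn <- renderMovie(sim$traces, sim$truth, cfg)
    truth <- cellData(sim$truth)
    rois <- ROISet(S4Vectors::DataFrame(
        id = truth$id, x = truth$x, y = truth$y, plane = truth$plane,
        z = truth$z, radius = 4, region = "unassigned"))
    ass <- assignRegions(rois, rn$masks, rn$labels)
    expect_equal(cellData(ass)$region, truth$region)
    counts <- S4Vectors::metadata(cellData(ass))$regionCounts
    expect_equal(counts[sort(unique(truth$region))],
                 table(truth$region)[sort(unique(truth$region))],
                 ignore_attr = TRUE)
    # a centroid on background label 0 is unassigned
    roisBg <- ROISet(S4Vectors::DataFrame(id = 1L, x = 1, y = 1, plane = 1L,
                                          z = 0, radius = 4,
                                          region = "x"))
    expect_equal(cellData(assignRegions(roisBg, rn$masks, rn$labels))$region,
                 "unassigned")
    expect_error(assignRegions(rois, rn$masks[1], rn$labels), "mask")
})

test_that("rigid registration recovers injected shifts and fixes the movie", {
    set.seed(1)
    base <- matrix(0, 48, 64)
    base[12:20, 20:28] <- 5; base[30:36, 45:51] <- 4
    base <- base + matrix(rnorm(48 * 64, sd = 0.1), 48)
    shiftBy <- function(m, dy, dx) {
        r <- pmin(pmax(seq_len(nrow(m)) - dy, 1), nrow(m))
        c <- pmin(pmax(seq_len(ncol(m)) - dx, 1), ncol(m))
        m[r, c]
    }
    frames <- array(0, dim = c(1, 6, 48, 64))
    for (t in 1:6) frames[1, t, , ] <- if (t > 4) shiftBy(base, 0, 3) else base
    reg <- registerFrames(Movie(frames, 3.86))
    expect_true(all(abs(reg$shifts$dx - c(0, 0, 0, 0, 3, 3)) <= 1))
    expect_true(all(abs(reg$shifts$dy) <= 1))
    # corrected frames agree away from the replicated border
    expect_equal(reg$movie@frames[1, 6, , 5:60],
                 reg$movie@frames[1, 1, , 5:60])

    still <- Movie(array(rep(base, 3), dim = c(1, 3, 48, 64)), 3.86)
    still@frames[1, 1, , ] <- base; still@frames[1, 2, , ] <- base
    still@frames[1, 3, , ] <- base
    reg0 <- registerFrames(still)
    expect_true(all(reg0$shifts$dy == 0 & reg0$shifts$dx == 0))
    expect_identical(reg0$movie@frames, still@frames)
    expect_error(registerFrames(Movie(array(1, dim = c(1, 1, 8, 8)), 2)),
                 "at least 2 frames")
})
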