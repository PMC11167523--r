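# Forward model for nuclear-calcium recordings: Poisson spiking filtered
# by a single-exponential indicator kernel, a distance-dependent shared
# latent drive, stimulus-locked responders / inhibited cells, optional
# planted activity bursts, and additive Gaussian noise.

#' Standard photic stimulation schedule
#'
#' Builds the whole-field light protocol used throughout the pipeline:
#' after 10 minutes of darkness, five 60-second stimuli with onsets at
#' minutes 10, 15, 20, 25 and 30 of the recording. Custom protocols can be
#' requested through `onsetMinutes` / `stimDuration`.
#'
#' @param config a [SimulationConfig][simulationConfig()]; only `duration`
#'   is consulted.
#' @param onsetMinutes stimulus onsets in minutes on the recording clock.
#' @param stimDuration duration of each stimulus, seconds.
#' @return A [StimulusSchedule()].
#' @examples
#' sched <- makeStimulusSchedule(simulationConfig())
#' onsets(sched)   # 600 900 1200 1500 1800
#' @export
makeStimulusSchedule <- function(config,
                                 onsetMinutes = c(10, 15, 20, 25, 30),
                                 stimDuration = 60) {
    stopifnot(is(config, "SimulationConfig"))
    on <- onsetMinutes * 60
    off <- on + stimDuration
    bad <- which(off > config@duration)
    if (length(bad))
        stop(sprintf(
            "stimulus %d (onset %g s, offset %g s) does not fit in a %g s recording",
            bad[1], on[bad[1]], off[bad[1]], config@duration))
    StimulusSchedule(on, off)
}

# Uniform dart-throwing placement inside one region box with a minimum
# pairwise 3-D separation.
.placeCells <- function(n, box, minSep, maxTries = 500L) {
    if (n == 0L)
        return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
    pos <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    placed <- 0L
    for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            p <- c(runif(1, box$x0, box$x1),
                   runif(1, box$y0, box$y1),
                   runif(1, box$z0, box$z1))
            if (placed == 0L) { ok <- TRUE; break }
            d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2)
            if (min(d2) >= minSep^2) { ok <- TRUE; break }
        }
        if (!ok)
            stop(sprintf(
                "could not place %d cells in region '%s' at %g um separation",
                n, box$region, minSep))
        pos[i, ] <- p
        placed <- placed + 1L
    }
    pos
}

# Discrete-time stationary variance of the filtered Poisson spike count:
# counts per frame ~ Poisson(rate * dt) convolved with a^m, a = exp(-dt/tau).
.calciumStats <- function(rate, dt, tau) {
    a <- exp(-dt / tau)
    list(mean = rate * dt / (1 - a),
         var = rate * dt / (1 - a^2),
         a = a)
}

#' Simulate a ground-truthed multi-cell recording
#'
#' Draws cell positions per region (uniform with a minimum separation),
#' assigns stimulus response classes, and generates fluorescence as
#' \deqn{F_i(t) = f_{0,i}\,(1 + A\,c_i(t) + \lambda L_i(t) + e_i(t) + b_i(t))
#'   + \epsilon_i(t),}
#' where `c` is a Poisson spike train filtered by the exponential calcium
#' kernel, `L` a shared latent drive whose pairwise correlation decays as
#' `exp(-d / correlationLength)`, `e` the stimulus-locked component
#' (ON-activated cells: `evokedAmplitude` while the light is on;
#' OFF-activated cells: the same amplitude for `offResponseDuration`
#' seconds after light offset; inhibited cells instead have their spike
#' rate multiplied by `suppressionFactor` during stimulation), `b` the
#' optional planted activity bursts, and `epsilon` white Gaussian noise
#' with sd `noiseSd * f0`.
#'
#' The same configuration and seed always reproduce the recording
#' bit-for-bit.
#'
#' @param config a [SimulationConfig][simulationConfig()].
#' @param schedule a [StimulusSchedule()], or `NULL`. With `NULL` and any
#'   positive evoked fraction the standard protocol is attempted; a pure
#'   spontaneous recording results when all evoked fractions are zero.
#' @param offResponseDuration duration (s) of the OFF-activated transient.
#' @return A list with elements `traces` (a [TraceMatrix()], raw
#'   fluorescence, per-cell metadata in `rowData`) and `truth`
#'   (a `GroundTruth`).
#' @examples
#' cfg <- simulationConfig(nCells = 5, duration = 60,
#'                         evokedFractions = c(0, 0, 0), seed = 42)
#' sim <- simulateTraces(cfg)
#' sim$traces
#' @export
simulateTraces <- function(config, schedule = NULL, offResponseDuration = 10) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (any(config@f0Range <= 0)) stop("f0 must be positive")
    if (config@noiseSd < 0) stop("noiseSd must be non-negative")

    geo <- config@regionGeometry
    nPerRegion <- config@nCells
    n <- sum(nPerRegion)
    if (n < 1L) stop("at least one cell required")
    dt <- 1 / config@volumeRate
    nT <- floor(config@duration * config@volumeRate)
    tAxis <- (seq_len(nT) - 1) * dt

    anyEvoked <- sum(config@evokedFractions) > 0
    if (is.null(schedule) && anyEvoked)
        schedule <- makeStimulusSchedule(config)

    set.seed(config@seed)

    ## --- geometry -------------------------------------------------------
    pos <- do.call(rbind, lapply(seq_len(nrow(geo)), function(i)
        .placeCells(nPerRegion[i], geo[i, ], config@minSeparation)))
    region <- rep(geo$region, nPerRegion)
    plane <- pmin(pmax(round(pos[, "z"] / config@planeSpacing) + 1L, 1L),
                  config@planeCount)

    ## --- response classes (counts fixed per region, membership random) --
    responseClass <- rep("none", n)
    offset <- 0L
    for (i in seq_len(nrow(geo))) {
        ni <- nPerRegion[i]
        if (ni == 0L) next
        counts <- round(config@evokedFractions * ni)
        while (sum(counts) > ni) counts[which.max(counts)] <-
            counts[which.max(counts)] - 1L
        idx <- offset + sample.int(ni, sum(counts))
        cls <- rep(c("on_activated", "off_activated", "inhibited"), counts)
        responseClass[idx] <- cls
        offset <- offset + ni
    }

    f0 <- runif(n, config@f0Range[1], config@f0Range[2])

    ## --- stimulus indicator ---------------------------------------------
    stimOn <- rep(FALSE, nT)
    offWin <- rep(FALSE, nT)
    if (!is.null(schedule)) {
        for (k in seq_along(schedule@onsets)) {
            stimOn <- stimOn | (tAxis >= schedule@onsets[k] &
                                tAxis < schedule@offsets[k])
            offWin <- offWin | (tAxis >= schedule@offsets[k] &
                                tAxis < schedule@offsets[k] + offResponseDuration)
        }
    }

    ## --- spikes and calcium ---------------------------------------------
    baseLambda <- config@spikeRate * dt
    lambda <- matrix(baseLambda, n, nT)
    if (any(stimOn) ) {
        inh <- responseClass == "inhibited"
        if (any(inh))
            lambda[inh, stimOn] <- baseLambda * config@suppressionFactor
    }
    spikes <- matrix(rpois(n * nT, lambda), n, nT)
    cs <- .calciumStats(config@spikeRate, dt, config@kernelDecayTau)
    calcium <- t(stats::filter(t(spikes), cs$a, method = "recursive"))
    dimnames(calcium) <- NULL

    ## --- shared latent drive --------------------------------------------
    latent <- NULL
    if (config@latentWeight > 0 && n > 1) {
        D <- as.matrix(dist(pos))
        K <- exp(-D / max(config@correlationLength, 1e-9))
        ch <- chol(K + diag(1e-8, n))
        latent <- crossprod(ch, matrix(rnorm(n * nT), n, nT))
    }

    ## --- evoked component -----------------------------------------------
    evoked <- matrix(0, n, nT)
    if (!is.null(schedule) && config@evokedAmplitude > 0) {
        onCells <- responseClass == "on_activated"
        offCells <- responseClass == "off_activated"
        if (any(onCells))
            evoked[onCells, stimOn] <- config@evokedAmplitude
        if (any(offCells))
            evoked[offCells, offWin] <- config@evokedAmplitude
    }

    ## --- planted activity bursts ----------------------------------------
    ## Burst state is constant over each 1-s bin of the recording clock
    ## (bin s spans [s - 0.5, s + 0.5)), cycling with period burstCycle
    ## seconds, so attainable active fractions are multiples of
    ## 1/burstCycle and the realized fraction equals the planted one.
    burst <- NULL
    trueActive <- rep(NA_real_, n)
    if (length(config@activeFractions)) {
        cyc <- max(2L, round(config@burstCycle))
        p <- rep_len(config@activeFractions, n)
        onSeconds <- round(p * cyc)
        if (any(onSeconds > 0.9 * cyc))
            warning("planted active fractions near 1 defeat the ",
                    "percentile baseline; keep them below 0.9")
        phase <- sample.int(cyc, n, replace = TRUE) - 1L
        secOfCycle <- round(tAxis) %% cyc      # frame -> 1-s bin -> cycle pos
        burst <- matrix(0, n, nT)
        for (i in seq_len(n)) {
            if (onSeconds[i] <= 0L) next
            on <- ((secOfCycle + phase[i]) %% cyc) < onSeconds[i]
            burst[i, on] <- config@burstAmplitude
        }
        trueActive <- onSeconds / cyc
    }

    ## --- assemble fluorescence ------------------------------------------
    signal <- config@transientAmplitude * calcium
    if (!is.null(latent)) signal <- signal + config@latentWeight * latent
    signal <- signal + evoked
    if (!is.null(burst)) signal <- signal + burst
    F <- f0 * (1 + signal)
    if (config@noiseSd > 0)
        F <- F + (config@noiseSd * f0) * matrix(rnorm(n * nT), n, nT)
    F <- pmax(F, 0.01 * f0)
    dimnames(F) <- NULL

    ## --- containers ------------------------------------------------------
    spikeLog <- lapply(seq_len(n), function(i) {
        cnt <- spikes[i, ]
        rep(tAxis[cnt > 0], cnt[cnt > 0])
    })
    cells <- DataFrame(
        id = seq_len(n),
        x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
        plane = as.integer(plane),
        region = region,
        responseClass = responseClass,
        f0 = f0,
        spikeCount = as.integer(rowSums(spikes)),
        trueActiveFraction = trueActive,
        row.names = paste0("cell", seq_len(n)))

    truth <- new("GroundTruth",
                 cells = cells,
                 spikes = spikeLog,
                 corrParams = list(
                     latentVar = config@latentWeight^2,
                     calciumVar = config@transientAmplitude^2 * cs$var,
                     noiseVar = config@noiseSd^2,
                     correlationLength = config@correlationLength),
                 schedule = schedule)

    traces <- TraceMatrix(F, volumeRate = config@volumeRate,
                          cells = cells[, c("id", "x", "y", "z", "plane",
                                            "region")],
                          signal = "raw")
    list(traces = traces, truth = truth)
}

#' Analytic pairwise trace correlation of the generator
#'
#' Under the forward model the only component shared between cells is the
#' latent drive, so the expected Pearson correlation between the raw
#' traces of two cells at distance `d` is
#' \deqn{r(d) = \frac{\lambda^2 e^{-d/\ell}}
#'   {A^2\,\mathrm{Var}(c) + \lambda^2 + \sigma^2},}
#' with `lambda` the latent weight, `ell` the correlation length, `A` the
#' per-spike transient amplitude, `Var(c)` the stationary variance of the
#' filtered spike train and `sigma` the noise sd (all in dF/F units).
#' Because dF/F is per-cell affine to within the slow baseline, the same
#' value applies to dF/F traces.
#'
#' @param truth a `GroundTruth` from [simulateTraces()].
#' @param distance inter-cell distance(s) in micrometres.
#' @return Expected Pearson correlation(s), same length as `distance`.
#' @export
analyticCorrelation <- function(truth, distance) {
    stopifnot(is(truth, "GroundTruth"))
    p <- truth@corrParams
    denom <- p$calciumVar + p$latentVar + p$noiseVar
    p$latentVar * exp(-distance / max(p$correlationLength, 1e-9)) / denom
}

#' Analytic correlations for all close cell pairs
#'
#' Enumerates all unordered within-region cell pairs up to `maxDistance`
#' (true 3-D positions) and attaches the model's expected correlation from
#' [analyticCorrelation()].
#'
#' @param truth a `GroundTruth`.
#' @param maxDistance maximum inter-cell distance, micrometres.
#' @return data.frame with columns `i, j, region, distance, r`.
#' @export
truePairCorrelations <- function(truth, maxDistance = 60) {
    cells <- truth@cells
    out <- list()
    for (reg in unique(cells$region)) {
        idx <- which(cells$region == reg)
        if (length(idx) < 2) next
        D <- as.matrix(dist(cbind(cells$x[idx], cells$y[idx], cells$z[idx])))
        sel <- which(upper.tri(D) & D <= maxDistance, arr.ind = TRUE)
        if (!nrow(sel)) next
        out[[reg]] <- data.frame(
            i = idx[sel[, 1]], j = idx[sel[, 2]], region = reg,
            distance = D[sel],
            r = analyticCorrelation(truth, D[sel]))
    }
    if (!length(out))
        return(data.frame(i = integer(), j = integer(),
                          region = character(), distance = numeric(),
                          r = numeric()))
    ans <- do.call(rbind, out)
    rownames(ans) <- NULL
    ans
}
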