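# Central S4 containers. Cells-by-time fluorescence lives in a
# SummarizedExperiment subclass so the usual Bioconductor accessors apply;
# the remaining containers are light S4 records with validity checks.

#' Brain regions used by the default simulated recordings
#'
#' The four brain parcels quantified by the pipeline: telencephalon,
#' habenula, optic tectum/thalamus and hindbrain.
#'
#' @return Character vector of region names.
#' @export
brainRegions <- function() {
    c("Telencephalon", "Habenula", "TeO/thalamus", "Hindbrain")
}

# Four side-by-side region strips filling the frame with a 10-um margin.
.defaultRegionGeometry <- function(planeCount = 8L, planeSpacing = 12,
                                   frameSize = c(512L, 256L), pxSize = 1,
                                   margin = 10) {
    zmax <- (planeCount - 1L) * planeSpacing
    W <- frameSize[1] * pxSize
    H <- frameSize[2] * pxSize
    w <- (W - 5 * margin) / 4
    x0 <- margin + (seq_len(4) - 1) * (w + margin)
    data.frame(
        region = brainRegions(),
        x0 = x0, x1 = x0 + w,
        y0 = rep(margin, 4), y1 = rep(H - margin, 4),
        z0 = rep(0, 4), z1 = rep(zmax, 4)
    )
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig", representation(
    nCells = "integer",
    regionGeometry = "data.frame",
    planeCount = "integer",
    volumeRate = "numeric",
    duration = "numeric",
    f0Range = "numeric",
    spikeRate = "numeric",
    kernelDecayTau = "numeric",
    transientAmplitude = "numeric",
    noiseSd = "numeric",
    evokedFractions = "numeric",
    evokedAmplitude = "numeric",
    suppressionFactor = "numeric",
    correlationLength = "numeric",
    latentWeight = "numeric",
    minSeparation = "numeric",
    planeSpacing = "numeric",
    frameSize = "integer",
    pxSize = "numeric",
    nucleusRadius = "numeric",
    pixelNoiseSd = "numeric",
    activeFractions = "numeric",
    burstAmplitude = "numeric",
    burstCycle = "numeric",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    geo <- object@regionGeometry
    need <- c("region", "x0", "x1", "y0", "y1", "z0", "z1")
    if (!all(need %in% names(geo)))
        msg <- c(msg, "regionGeometry must have columns region, x0..z1")
    if (length(object@nCells) != nrow(geo))
        msg <- c(msg, "nCells must give one count per region")
    if (any(object@nCells < 0L))
        msg <- c(msg, "nCells must be non-negative")
    nonneg <- c(spikeRate = object@spikeRate, tau = object@kernelDecayTau,
                amp = object@transientAmplitude, noise = object@noiseSd,
                evoked = object@evokedAmplitude, corlen = object@correlationLength,
                latent = object@latentWeight)
    if (any(nonneg < 0)) msg <- c(msg, "rates and amplitudes must be >= 0")
    if (any(object@f0Range <= 0)) msg <- c(msg, "f0Range must be positive")
    if (object@volumeRate <= 0) msg <- c(msg, "volumeRate must be positive")
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    ef <- object@evokedFractions
    if (length(ef) != 3L || any(ef < 0) || any(ef > 1) || sum(ef) > 1)
        msg <- c(msg, paste("evokedFractions must be three fractions",
                            "(on, off, inhibited) in [0,1] summing to <= 1"))
    if (object@suppressionFactor < 0 || object@suppressionFactor > 1)
        msg <- c(msg, "suppressionFactor must be in [0,1]")
    if (length(object@activeFractions) &&
        (any(object@activeFractions < 0) || any(object@activeFractions > 1)))
        msg <- c(msg, "activeFractions must be proportions in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic-recording generator
#'
#' Bundles every knob of the forward model that emulates nuclear-calcium
#' recordings: geometry of the imaged volume, acquisition constants,
#' baseline fluorescence, spiking statistics, the calcium-indicator decay
#' kernel, stimulus-locked response classes, the distance-dependent shared
#' latent drive, and noise.
#'
#' @param nCells integer, cells per region (recycled across regions).
#' @param regionGeometry data.frame with columns `region, x0, x1, y0, y1,
#'   z0, z1` giving per-region bounding boxes in micrometres.
#' @param planeCount number of imaging planes per volume.
#' @param volumeRate volume acquisition rate in Hz.
#' @param duration recording duration in seconds.
#' @param f0Range range (min, max) of per-cell baseline fluorescence,
#'   arbitrary units, strictly positive.
#' @param spikeRate spontaneous Poisson spike rate per cell, Hz.
#' @param kernelDecayTau decay time constant of the single-exponential
#'   calcium kernel, seconds. Nuclear GCaMP6s is slow, hence the default.
#' @param transientAmplitude fractional fluorescence change per spike
#'   (dF/F units).
#' @param noiseSd additive Gaussian noise standard deviation as a fraction
#'   of each cell's baseline fluorescence.
#' @param evokedFractions three fractions (ON-activated, OFF-activated,
#'   inhibited) of cells per region; must sum to at most 1.
#' @param evokedAmplitude amplitude of the stimulus-locked response in
#'   dF/F units.
#' @param suppressionFactor multiplicative factor applied to the spike rate
#'   of inhibited cells while the stimulus is on.
#' @param correlationLength distance scale (micrometres) of the shared
#'   latent drive; pairwise latent correlation decays as
#'   `exp(-d / correlationLength)`.
#' @param latentWeight standard deviation of the shared latent component in
#'   dF/F units (0 disables it).
#' @param minSeparation minimum 3-D distance between cell centres,
#'   micrometres.
#' @param planeSpacing axial distance between imaging planes, micrometres.
#' @param frameSize frame size as (width, height) in pixels.
#' @param pxSize lateral pixel size in micrometres.
#' @param nucleusRadius rendered nucleus radius in pixels.
#' @param pixelNoiseSd additive Gaussian pixel noise of rendered movies
#'   (intensity units).
#' @param activeFractions optional per-cell target active fractions (values
#'   in [0,1], recycled over cells); when set, cells receive a burst
#'   component that keeps them above the activity threshold for that
#'   proportion of time.
#' @param burstAmplitude dF/F amplitude of the planted bursts (well above
#'   the activity threshold of dF/F = 3).
#' @param burstCycle burst pattern period in whole seconds; planted
#'   fractions are realized on a 1-second grid within each cycle, so
#'   attainable fractions are multiples of `1/burstCycle`. Fractions above
#'   ~0.9 defeat the moving-percentile baseline and trigger a warning.
#' @param seed integer seed; identical configurations with identical seeds
#'   yield bit-identical recordings.
#' @return A `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(nCells = 10, duration = 120, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nCells = 125L,
                             regionGeometry = NULL,
                             planeCount = 8L,
                             volumeRate = 3.86,
                             duration = 2400,
                             f0Range = c(80, 120),
                             spikeRate = 1.0,
                             kernelDecayTau = 3.5,
                             transientAmplitude = 0.15,
                             noiseSd = 0.1,
                             evokedFractions = c(on = 0.3, off = 0.1,
                                                 inhibited = 0.1),
                             evokedAmplitude = 0.5,
                             suppressionFactor = 0.1,
                             correlationLength = 20,
                             latentWeight = 0.2,
                             minSeparation = 8,
                             planeSpacing = 12,
                             frameSize = c(512L, 256L),
                             pxSize = 1,
                             nucleusRadius = 4,
                             pixelNoiseSd = 0,
                             activeFractions = numeric(0),
                             burstAmplitude = 5,
                             burstCycle = 25,
                             seed = 1L) {
    if (is.null(regionGeometry))
        regionGeometry <- .defaultRegionGeometry(as.integer(planeCount),
                                                 planeSpacing,
                                                 as.integer(frameSize),
                                                 pxSize)
    nCells <- rep_len(as.integer(nCells), nrow(regionGeometry))
    new("SimulationConfig",
        nCells = nCells,
        regionGeometry = regionGeometry,
        planeCount = as.integer(planeCount),
        volumeRate = volumeRate,
        duration = duration,
        f0Range = range(f0Range),
        spikeRate = spikeRate,
        kernelDecayTau = kernelDecayTau,
        transientAmplitude = transientAmplitude,
        noiseSd = noiseSd,
        evokedFractions = setNames(as.numeric(evokedFractions),
                                   c("on", "off", "inhibited")),
        evokedAmplitude = evokedAmplitude,
        suppressionFactor = suppressionFactor,
        correlationLength = correlationLength,
        latentWeight = latentWeight,
        minSeparation = minSeparation,
        planeSpacing = planeSpacing,
        frameSize = as.integer(frameSize),
        pxSize = pxSize,
        nucleusRadius = nucleusRadius,
        pixelNoiseSd = pixelNoiseSd,
        activeFractions = as.numeric(activeFractions),
        burstAmplitude = burstAmplitude,
        burstCycle = burstCycle,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", sum(object@nCells), "cells in",
        nrow(object@regionGeometry), "regions\n")
    cat("  duration", object@duration, "s at", object@volumeRate,
        "Hz (", object@planeCount, "planes )\n")
    cat("  spikeRate", object@spikeRate, "Hz, tau", object@kernelDecayTau,
        "s, noiseSd", object@noiseSd, "\n")
    cat("  evoked fractions on/off/inh:",
        paste(object@evokedFractions, collapse = "/"),
        " amplitude", object@evokedAmplitude, "\n")
    cat("  latentWeight", object@latentWeight, " correlationLength",
        object@correlationLength, "um, seed", object@seed, "\n")
})

#' @rdname StimulusSchedule
#' @export
setClass("StimulusSchedule", representation(
    onsets = "numeric",
    offsets = "numeric"
))

setValidity("StimulusSchedule", function(object) {
    msg <- character()
    if (length(object@onsets) != length(object@offsets))
        msg <- c(msg, "onsets and offsets must have equal length")
    if (length(object@onsets) > 1 && any(diff(object@onsets) <= 0))
        msg <- c(msg, "onsets must be strictly increasing")
    if (any(object@offsets <= object@onsets))
        msg <- c(msg, "each offset must be after its onset")
    if (length(msg)) msg else TRUE
})

#' Stimulus schedule on the recording clock
#'
#' Onset and offset times (seconds) of a train of whole-field light
#' stimuli, ordered in time.
#'
#' @param onsets stimulus onset times, seconds, strictly increasing.
#' @param offsets stimulus offset times, seconds, pairwise after onsets.
#' @return A `StimulusSchedule` object.
#' @seealso [makeStimulusSchedule()] for the standard photic protocol.
#' @export
StimulusSchedule <- function(onsets, offsets) {
    new("StimulusSchedule", onsets = as.numeric(onsets),
        offsets = as.numeric(offsets))
}

setMethod("show", "StimulusSchedule", function(object) {
    cat("StimulusSchedule with", length(object@onsets), "stimuli\n")
    cat("  onsets (s): ", paste(object@onsets, collapse = ", "), "\n")
    cat("  offsets (s):", paste(object@offsets, collapse = ", "), "\n")
})

#' @rdname Movie
#' @export
setClass("Movie", representation(
    frames = "array",
    volumeRate = "numeric",
    planeSpacing = "numeric",
    pxSize = "numeric"
))

setValidity("Movie", function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 4L)
        msg <- c(msg, "frames must be a plane x time x height x width array")
    if (any(dim(object@frames) < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    if (object@volumeRate <= 0) msg <- c(msg, "volumeRate must be positive")
    if (length(msg)) msg else TRUE
})

#' Multi-plane fluorescence movie
#'
#' A plane-resolved time series with its spatial and temporal calibration.
#' Frames are stored as a 4-D array indexed `[plane, time, row, column]`;
#' rows run along y and columns along x, 1-based, with the cell centroid
#' coordinate convention `column = floor(x / pxSize) + 1`.
#'
#' @param frames 4-D numeric array, `plane x time x height x width`.
#' @param volumeRate volumes per second (Hz).
#' @param planeSpacing axial plane spacing in micrometres.
#' @param pxSize lateral pixel size in micrometres.
#' @return A `Movie` object.
#' @export
Movie <- function(frames, volumeRate, planeSpacing = 12, pxSize = 1) {
    new("Movie", frames = frames, volumeRate = volumeRate,
        planeSpacing = planeSpacing, pxSize = pxSize)
}

setMethod("show", "Movie", function(object) {
    d <- dim(object@frames)
    cat(sprintf("Movie: %d planes x %d volumes, %d x %d px\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  volumeRate %.3g Hz, planeSpacing %.3g um, px %.3g um\n",
                object@volumeRate, object@planeSpacing, object@pxSize))
})

#' @rdname ROISet
#' @export
setClass("ROISet", representation(cells = "DFrame"))

setValidity("ROISet", function(object) {
    need <- c("id", "x", "y", "plane", "z", "radius", "region")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Set of segmented neuronal nuclei
#'
#' One row per detected (or simulated) cell: centroid in micrometres
#' (`x`, `y`, with `z = (plane - 1) * planeSpacing`), the plane index, the
#' footprint radius in pixels, and the brain-region label
#' (`"unassigned"` when the cell falls outside every labelled region).
#'
#' @param cells a `DataFrame`/data.frame with columns `id, x, y, plane, z,
#'   radius, region`.
#' @return An `ROISet`.
#' @export
ROISet <- function(cells) {
    cells <- as(cells, "DFrame")
    if (!"region" %in% colnames(cells)) cells$region <- "unassigned"
    new("ROISet", cells = cells)
}

setMethod("show", "ROISet", function(object) {
    cat("ROISet with", nrow(object@cells), "cells\n")
    tab <- table(object@cells$region)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
})

#' @rdname TraceMatrix
#' @export
setClass("TraceMatrix", contains = "SummarizedExperiment")

setValidity("TraceMatrix", function(object) {
    msg <- character()
    if (!length(assays(object)))
        msg <- c(msg, "TraceMatrix needs one assay of traces")
    md <- metadata(object)
    if (is.null(md$volumeRate) || md$volumeRate <= 0)
        msg <- c(msg, "metadata volumeRate must be positive")
    if (is.null(md$signal) || !md$signal %in% c("raw", "dff"))
        msg <- c(msg, "metadata signal must be 'raw' or 'dff'")
    v <- assay(object)
    if (anyNA(v)) msg <- c(msg, "traces must not contain missing values")
    if (identical(md$signal, "raw") && length(v) && min(v) <= 0)
        msg <- c(msg, "raw fluorescence must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' Cells-by-timepoints fluorescence matrix
#'
#' A `SummarizedExperiment` subclass holding one cells x timepoints assay
#' (raw fluorescence or dF/F, flagged in `signalType()`), per-cell metadata
#' (3-D position, plane, region) as `rowData`, and the acquisition rate.
#'
#' @param values numeric matrix, cells x timepoints.
#' @param volumeRate sampling rate of the columns, Hz.
#' @param cells optional per-cell `DataFrame` (`rowData`).
#' @param signal `"raw"` or `"dff"`.
#' @return A `TraceMatrix`.
#' @export
TraceMatrix <- function(values, volumeRate, cells = NULL, signal = "raw") {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("cell", seq_len(nrow(values)))
    se <- SummarizedExperiment(
        assays = list(traces = values),
        rowData = if (is.null(cells)) DataFrame(row.names = rownames(values))
                  else as(cells, "DFrame"))
    metadata(se) <- list(volumeRate = volumeRate, signal = signal)
    new("TraceMatrix", se)
}

setMethod("show", "TraceMatrix", function(object) {
    cat(sprintf("TraceMatrix: %d cells x %d timepoints (%s) at %.3g Hz\n",
                nrow(object), ncol(object), signalType(object),
                volumeRate(object)))
    if ("region" %in% colnames(rowData(object))) {
        tab <- table(rowData(object)$region)
        cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
})

#' Ground truth of a simulated recording
#'
#' One record per simulated cell (position, region, response class,
#' baseline fluorescence, spike count, planted active fraction), the full
#' spike log, the parameters needed for the analytic pairwise-correlation
#' formula, and the stimulus schedule used. Created by
#' [simulateTraces()].
#'
#' @name GroundTruth-class
#' @aliases GroundTruth
#' @export
setClass("GroundTruth", representation(
    cells = "DFrame",
    spikes = "list",
    corrParams = "list",
    schedule = "ANY"
))

setValidity("GroundTruth", function(object) {
    need <- c("id", "x", "y", "z", "plane", "region", "responseClass")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells must have columns:", paste(need, collapse = ", ")))
    if (length(object@spikes) != nrow(object@cells))
        return("one spike-time vector per cell required")
    TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth for", nrow(object@cells), "simulated cells\n")
    tab <- table(object@cells$responseClass)
    cat("  response classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @rdname ERGRecording
#' @export
setClass("ERGRecording", representation(
    voltage = "numeric",
    sampleRate = "numeric",
    stimOnsets = "numeric",
    stimDuration = "numeric",
    trueAmplitude = "numeric"
))

setValidity("ERGRecording", function(object) {
    msg <- character()
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
    if (length(object@stimOnsets) > 1 && any(diff(object@stimOnsets) <= 0))
        msg <- c(msg, "stimulus onsets must be strictly increasing")
    dur <- length(object@voltage) / object@sampleRate
    if (length(object@stimOnsets) && max(object@stimOnsets) >= dur)
        msg <- c(msg, "stimulus onsets must lie inside the recording")
    if (length(msg)) msg else TRUE
})

#' Single-eye electroretinogram recording
#'
#' A voltage trace (microvolts) with its digitization rate and the light
#' stimulus train. `trueAmplitude` carries the generator's ground-truth
#' ON-response amplitude for synthetic traces and is `NA` for real data.
#'
#' @param voltage numeric vector of voltages, microvolts.
#' @param sampleRate samples per second, Hz.
#' @param stimOnsets stimulus onset times, seconds.
#' @param stimDuration duration of each stimulus, seconds.
#' @param trueAmplitude ground-truth 0-200 ms mean amplitude (synthetic
#'   traces only).
#' @return An `ERGRecording`.
#' @export
ERGRecording <- function(voltage, sampleRate, stimOnsets,
                         stimDuration = 1, trueAmplitude = NA_real_) {
    new("ERGRecording", voltage = as.numeric(voltage),
        sampleRate = sampleRate, stimOnsets = as.numeric(stimOnsets),
        stimDuration = stimDuration, trueAmplitude = trueAmplitude)
}

setMethod("show", "ERGRecording", function(object) {
    cat(sprintf("ERGRecording: %.3g s at %g Hz, %d stimuli\n",
                length(object@voltage) / object@sampleRate,
                object@sampleRate, length(object@stimOnsets)))
})

#' Evoked-response classification result
#'
#' Per-cell trial-averaged dF/F, response amplitudes and
#' activated/inhibited/none classes for the ON and OFF conditions, plus
#' the per-region summary table. Created by [evokedResponses()].
#'
#' @name EvokedResult-class
#' @aliases EvokedResult
#' @export
setClass("EvokedResult", representation(
    cells = "DFrame",
    regions = "data.frame",
    nTrials = "integer",
    avgTime = "numeric",
    avgDff = "matrix",
    windows = "list"
))

setMethod("show", "EvokedResult", function(object) {
    cat("EvokedResult:", nrow(object@cells), "cells,",
        object@nTrials, "trials averaged\n")
    cat("  ON  activated:", sum(object@cells$onClass == "activated"),
        " inhibited:", sum(object@cells$onClass == "inhibited"), "\n")
    cat("  OFF activated:", sum(object@cells$offClass == "activated"),
        " inhibited:", sum(object@cells$offClass == "inhibited"), "\n")
})

#' Spontaneous-activity metrics
#'
#' Per-cell active fractions and categories (highly active / inactive /
#' intermediate) with per-region summaries and cumulative frequency
#' distributions. Created by [regionActivitySummary()] /
#' [spontaneousActivity()].
#'
#' @name ActivityMetrics-class
#' @aliases ActivityMetrics
#' @export
setClass("ActivityMetrics", representation(
    cells = "DFrame",
    regions = "data.frame",
    cdf = "matrix",
    grid = "numeric"
))

setMethod("show", "ActivityMetrics", function(object) {
    cat("ActivityMetrics:", nrow(object@cells), "cells\n")
    tab <- table(object@cells$category)
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

#' Correlation-versus-distance profile
#'
#' Per-region distance-binned mean positive and negative Pearson
#' correlations with within-60-um scalar summaries. Created by
#' [correlationVsDistance()].
#'
#' @name CorrelationProfile-class
#' @aliases CorrelationProfile
#' @export
setClass("CorrelationProfile", representation(
    bins = "data.frame",
    summary = "data.frame",
    maxDistance = "numeric",
    dropped = "integer"
))

setMethod("show", "CorrelationProfile", function(object) {
    cat("CorrelationProfile up to", object@maxDistance, "um\n")
    print(object@summary)
})

#' Two-group comparison result
#'
#' Rank-sum statistic, two-sided p-value, significance stars and group
#' summaries for one per-fish metric. Created by [wilcoxonRankSum()].
#'
#' @name GroupComparison-class
#' @aliases GroupComparison
#' @export
setClass("GroupComparison", representation(
    metric = "character",
    groupA = "numeric",
    groupB = "numeric",
    statistic = "numeric",
    pValue = "numeric",
    method = "character",
    stars = "character",
    degenerate = "logical",
    summary = "data.frame"
))

setValidity("GroupComparison", function(object) {
    msg <- character()
    if (!length(object@groupA) || !length(object@groupB))
        msg <- c(msg, "both groups must be non-empty")
    if (object@pValue <= 0 || object@pValue > 1)
        msg <- c(msg, "p-value must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("Wilcoxon rank-sum [%s]: W = %g, p = %.4g %s (%s)\n",
                object@metric, object@statistic, object@pValue,
                object@stars, object@method))
    print(object@summary)
})
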