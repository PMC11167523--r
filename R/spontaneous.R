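# Ongoing (spontaneous) activity in darkness: ongoing-window selection,
# dF/F against a moving 8th-percentile baseline, 1 Hz resampling, the
# 4-times-baseline activity threshold, and per-region summaries.

#' Select the ongoing-activity window
#'
#' Returns the volumes used for spontaneous-activity quantification
#' (default 460 through 2304 inclusive, 1-based, i.e. 1845 volumes after
#' discarding the initial laser-onset artefact period).
#'
#' @param traces a [TraceMatrix()].
#' @param frames two integers, first and last volume (1-based, inclusive).
#' @return The subsetted [TraceMatrix()].
#' @export
selectOngoingFrames <- function(traces, frames = c(460L, 2304L)) {
    stopifnot(is(traces, "TraceMatrix"), length(frames) == 2L)
    if (ncol(traces) < frames[2])
        stop(sprintf("recording has %d volumes; need at least %d",
                     ncol(traces), frames[2]))
    traces[, frames[1]:frames[2]]
}

#' dF/F with a moving 8th-percentile baseline
#'
#' The baseline `B(t)` is the 8th percentile of the raw fluorescence over
#' a centred moving window (truncated at the edges; percentile by linear
#' interpolation between order statistics), and
#' `dF/F(t) = (F(t) - B(t)) / B(t)`.
#'
#' @param traces a raw [TraceMatrix()].
#' @param window window length, seconds.
#' @param prob baseline percentile (0.08 = 8th percentile).
#' @return List with `dff` (a [TraceMatrix()], signal `"dff"`) and
#'   `baseline` (cells x timepoints matrix).
#' @export
dffPercentileBaseline <- function(traces, window = 30, prob = 0.08) {
    stopifnot(is(traces, "TraceMatrix"))
    if (signalType(traces) != "raw")
        stop("dffPercentileBaseline expects raw fluorescence")
    rate <- volumeRate(traces)
    wFrames <- max(3L, round(window * rate))
    half <- max(1L, floor(wFrames / 2))
    F <- traceValues(traces)
    B <- t(roll_quantile_col(t(F), half, prob))
    if (any(B <= 0)) stop("non-positive moving baseline")
    dff <- (F - B) / B
    dimnames(dff) <- dimnames(F)
    list(dff = TraceMatrix(dff, volumeRate = rate,
                           cells = cellData(traces), signal = "dff"),
         baseline = B)
}

#' Resample traces to one sample per second
#'
#' Linear interpolation at integer seconds of the recording clock (sample
#' `k` of the input sits at `(k - 1) / volumeRate` seconds). Constant
#' inputs map to the same constant and linear ramps stay linear.
#'
#' @param x a [TraceMatrix()] or a cells x timepoints matrix.
#' @param volumeRate input sampling rate, Hz; taken from `x` when it is a
#'   [TraceMatrix()].
#' @return Same type as `x`, sampled at 1 Hz.
#' @export
resample1fps <- function(x, volumeRate = NULL) {
    isTM <- is(x, "TraceMatrix")
    if (isTM) volumeRate <- volumeRate(x)
    if (is.null(volumeRate) || volumeRate <= 1)
        stop("volumeRate must be > 1 Hz")
    v <- if (isTM) traceValues(x) else as.matrix(x)
    tIn <- (seq_len(ncol(v)) - 1) / volumeRate
    tOut <- 0:floor(tIn[length(tIn)])
    out <- t(apply(v, 1, function(row)
        approx(tIn, row, xout = tOut, method = "linear")$y))
    colnames(out) <- NULL
    if (isTM)
        TraceMatrix(out, volumeRate = 1, cells = cellData(x),
                    signal = signalType(x))
    else out
}

#' Per-cell activity fractions
#'
#' A cell counts as active in a given second when its fluorescence exceeds
#' four times the moving-percentile baseline (`F > threshold * B`,
#' equivalently dF/F > 3). Cells are categorised as `highly_active`
#' (active more than 50% of the time), `inactive` (less than 10%), or
#' `intermediate`.
#'
#' @param F raw fluorescence resampled to 1 Hz (matrix or
#'   [TraceMatrix()]).
#' @param B matching baseline resampled to 1 Hz.
#' @param threshold multiple of the baseline defining activity.
#' @return `DataFrame` with columns `activeFraction` (percent) and
#'   `category`.
#' @export
activityFraction <- function(F, B, threshold = 4) {
    Fv <- if (is(F, "TraceMatrix")) traceValues(F) else as.matrix(F)
    Bv <- if (is(B, "TraceMatrix")) traceValues(B) else as.matrix(B)
    if (!identical(dim(Fv), dim(Bv)))
        stop("fluorescence and baseline dimensions differ")
    active <- Fv > threshold * Bv
    frac <- 100 * rowMeans(active)
    DataFrame(
        activeFraction = frac,
        category = ifelse(frac > 50, "highly_active",
                   ifelse(frac < 10, "inactive", "intermediate")),
        row.names = rownames(Fv))
}

#' Per-region spontaneous-activity summary
#'
#' Percent of highly-active and inactive cells per region together with
#' the cumulative frequency distribution of per-cell active fractions on
#' a fixed 0-100% grid (1% steps).
#'
#' @param metrics per-cell `DataFrame` from [activityFraction()].
#' @param regions per-cell region labels (character vector, or an
#'   [ROISet()]/[TraceMatrix()] carrying them).
#' @return An [ActivityMetrics][ActivityMetrics-class]: per-cell table,
#'   per-region table and the cumulative distribution matrix (grid x
#'   regions, percent of cells with active fraction <= grid value).
#' @export
regionActivitySummary <- function(metrics, regions) {
    if (is(regions, "ROISet") || is(regions, "TraceMatrix"))
        regions <- cellData(regions)$region
    stopifnot(length(regions) == nrow(metrics))
    metrics$region <- regions
    grid <- 0:100
    regs <- unique(regions)
    cdf <- matrix(NA_real_, length(grid), length(regs),
                  dimnames = list(grid, regs))
    rows <- list()
    for (reg in regs) {
        fr <- metrics$activeFraction[regions == reg]
        n <- length(fr)
        rows[[reg]] <- data.frame(
            region = reg, n = n,
            pctHighlyActive = if (n) 100 * mean(fr > 50) else 0,
            pctInactive = if (n) 100 * mean(fr < 10) else 0,
            empty = n == 0L)
        if (n) cdf[, reg] <- 100 * vapply(grid, function(g) mean(fr <= g),
                                          numeric(1))
    }
    new("ActivityMetrics", cells = metrics,
        regions = do.call(rbind, c(rows, list(make.row.names = FALSE))),
        cdf = cdf, grid = as.numeric(grid))
}

#' Spontaneous-activity pipeline
#'
#' Ongoing-window selection, moving 8th-percentile dF/F, 1 Hz resampling
#' of fluorescence and baseline, activity thresholding and per-region
#' summary in one call.
#'
#' @inheritParams dffPercentileBaseline
#' @inheritParams selectOngoingFrames
#' @inheritParams activityFraction
#' @return List with `metrics` (an
#'   [ActivityMetrics][ActivityMetrics-class]) and `dff1` (the 1 Hz dF/F
#'   [TraceMatrix()], as used by the correlation analysis).
#' @export
spontaneousActivity <- function(traces, frames = c(460L, 2304L),
                                window = 30, threshold = 4) {
    ongoing <- selectOngoingFrames(traces, frames)
    pb <- dffPercentileBaseline(ongoing, window = window)
    F1 <- resample1fps(traceValues(ongoing), volumeRate(ongoing))
    B1 <- resample1fps(pb$baseline, volumeRate(ongoing))
    dff1 <- resample1fps(pb$dff)
    af <- activityFraction(F1, B1, threshold = threshold)
    list(metrics = regionActivitySummary(af, cellData(traces)$region),
         dff1 = dff1)
}
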