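# Evoked (photic) response quantification: trial averaging around each
# stimulus, dF/F against the 5-s pre-stimulus baseline, 2-SD
# activated/inhibited classification for the ON and OFF windows, and
# per-region summaries.

#' Trial-average traces around each stimulus
#'
#' Cuts a window from `pre` seconds before each stimulus onset to `post`
#' seconds after its offset and averages the windows pointwise across
#' trials, aligned on onset. Window edges are converted to whole volumes
#' (onset floored, end ceiled).
#'
#' @param traces a raw [TraceMatrix()].
#' @param schedule a [StimulusSchedule()]; stimuli must share one duration.
#' @param pre pre-onset baseline span, seconds.
#' @param post span after stimulus offset, seconds.
#' @return List with `avg` (cells x window matrix), `time` (seconds
#'   relative to onset), `nTrials`, `stimDuration`, `preFrames`.
#' @export
trialAverage <- function(traces, schedule, pre = 5, post = 10) {
    stopifnot(is(traces, "TraceMatrix"), is(schedule, "StimulusSchedule"))
    rate <- volumeRate(traces)
    dur <- unique(round(offsets(schedule) - onsets(schedule), 9))
    if (length(dur) != 1L)
        stop("trialAverage requires equal stimulus durations")
    nT <- ncol(traces)
    preFrames <- ceiling(pre * rate)
    postFrames <- ceiling((dur + post) * rate)
    L <- preFrames + postFrames
    vals <- traceValues(traces)
    acc <- matrix(0, nrow(traces), L)
    for (k in seq_along(onsets(schedule))) {
        onsetIdx <- floor(onsets(schedule)[k] * rate) + 1L
        win <- (onsetIdx - preFrames):(onsetIdx + postFrames - 1L)
        if (win[1] < 1L || win[length(win)] > nT)
            stop(sprintf(
                "trial %d window (volumes %d..%d) outside recording (1..%d)",
                k, win[1], win[length(win)], nT))
        acc <- acc + vals[, win, drop = FALSE]
    }
    list(avg = acc / length(onsets(schedule)),
         time = ((seq_len(L) - 1L) - preFrames) / rate,
         nTrials = length(onsets(schedule)),
         stimDuration = dur,
         preFrames = preFrames)
}

#' dF/F of an averaged trial against its pre-stimulus baseline
#'
#' `dF/F(t) = (F(t) - Fbar_pre) / Fbar_pre`, with `Fbar_pre` the mean over
#' the pre-onset window; the baseline SD is the standard deviation of
#' dF/F over that same window.
#'
#' @param trial output of [trialAverage()].
#' @return `trial` with elements `dff` (cells x window), `baselineSd`
#'   (per cell) added and `avg` removed.
#' @export
dffFromPreBaseline <- function(trial) {
    pre <- trial$time < 0
    if (sum(pre) < 2L) stop("pre-stimulus window needs at least 2 samples")
    f0 <- rowMeans(trial$avg[, pre, drop = FALSE])
    if (any(f0 <= 0))
        stop("non-positive pre-stimulus baseline mean; raw traces required")
    dff <- sweep(sweep(trial$avg, 1, f0, "-"), 1, f0, "/")
    trial$dff <- dff
    trial$baselineSd <- apply(dff[, pre, drop = FALSE], 1, sd)
    trial$avg <- NULL
    trial
}

#' Classify cells as activated / inhibited / none
#'
#' The response amplitude is the mean dF/F over the `window` seconds
#' following light onset (`"ON"`) or offset (`"OFF"`); a cell is
#' `activated` when the amplitude exceeds `+2 * baselineSd`, `inhibited`
#' below `-2 * baselineSd`, and `none` otherwise. Cells with a zero
#' baseline SD and a nonzero amplitude (noiseless degenerate input) are
#' classified by amplitude sign and flagged.
#'
#' @param trial output of [dffFromPreBaseline()].
#' @param condition `"ON"` or `"OFF"`.
#' @param window response window length, seconds.
#' @return `DataFrame` with columns `amplitude`, `class`, `flagged`.
#' @export
classifyResponse <- function(trial, condition = c("ON", "OFF"), window = 10) {
    condition <- match.arg(condition)
    start <- if (condition == "ON") 0 else trial$stimDuration
    sel <- trial$time >= start & trial$time < start + window
    if (!any(sel) || max(trial$time) < start + window - 1 / 2)
        stop("response window does not fit in the averaged trial")
    amp <- rowMeans(trial$dff[, sel, drop = FALSE])
    sdb <- trial$baselineSd
    cls <- rep("none", length(amp))
    cls[amp > 2 * sdb] <- "activated"
    cls[amp < -2 * sdb] <- "inhibited"
    flagged <- sdb == 0 & amp != 0
    cls[flagged & amp > 0] <- "activated"
    cls[flagged & amp < 0] <- "inhibited"
    DataFrame(amplitude = amp, class = cls, flagged = flagged)
}

#' Full evoked-response analysis
#'
#' Trial averaging, baseline dF/F, ON and OFF classification and region
#' summary in one call.
#'
#' @inheritParams trialAverage
#' @param window response window length, seconds.
#' @return An [EvokedResult][EvokedResult-class].
#' @export
evokedResponses <- function(traces, schedule, pre = 5, post = 10,
                            window = 10) {
    trial <- dffFromPreBaseline(trialAverage(traces, schedule, pre, post))
    on <- classifyResponse(trial, "ON", window)
    off <- classifyResponse(trial, "OFF", window)
    rd <- cellData(traces)
    cells <- DataFrame(
        id = if ("id" %in% colnames(rd)) rd$id else seq_len(nrow(traces)),
        region = if ("region" %in% colnames(rd)) rd$region
                 else rep("unassigned", nrow(traces)),
        onAmplitude = on$amplitude, onClass = on$class,
        offAmplitude = off$amplitude, offClass = off$class,
        baselineSd = trial$baselineSd,
        flagged = on$flagged | off$flagged,
        row.names = rownames(traces))
    res <- new("EvokedResult", cells = cells,
               regions = data.frame(), nTrials = as.integer(trial$nTrials),
               avgTime = trial$time, avgDff = trial$dff,
               windows = list(pre = pre, post = post, window = window,
                              stimDuration = trial$stimDuration))
    res@regions <- regionSummary(res)
    res
}

#' Per-region evoked summary
#'
#' Mean response amplitude and percentages of activated and inhibited
#' cells per region and condition. Unassigned cells are excluded from the
#' region rows; their count is reported in an attribute.
#'
#' @param evoked an [EvokedResult][EvokedResult-class].
#' @param rois optional [ROISet()] supplying region labels (otherwise the
#'   labels carried by the result are used).
#' @return data.frame with columns `region, condition, n, meanAmplitude,
#'   pctActivated, pctInhibited`; `attr(, "nUnassigned")` reports the
#'   excluded cells.
#' @export
regionSummary <- function(evoked, rois = NULL) {
    stopifnot(is(evoked, "EvokedResult"))
    cells <- evoked@cells
    if (!is.null(rois)) cells$region <- cellData(rois)$region
    keep <- cells$region != "unassigned"
    nUnassigned <- sum(!keep)
    cells <- cells[keep, , drop = FALSE]
    regs <- unique(cells$region)
    rows <- list()
    for (reg in regs) {
        sub <- cells[cells$region == reg, , drop = FALSE]
        for (cond in c("ON", "OFF")) {
            amp <- if (cond == "ON") sub$onAmplitude else sub$offAmplitude
            cls <- if (cond == "ON") sub$onClass else sub$offClass
            n <- nrow(sub)
            rows[[length(rows) + 1L]] <- data.frame(
                region = reg, condition = cond, n = n,
                meanAmplitude = if (n) mean(amp) else NA_real_,
                pctActivated = if (n) 100 * mean(cls == "activated") else 0,
                pctInhibited = if (n) 100 * mean(cls == "inhibited") else 0)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(region = character(), condition = character(),
                           n = integer(), meanAmplitude = numeric(),
                           pctActivated = numeric(), pctInhibited = numeric())
    attr(out, "nUnassigned") <- nUnassigned
    out
}
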