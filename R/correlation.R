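# Pairwise Pearson correlation between cells within each brain region,
# related to 3-D inter-cell distance, with sign-restricted bin means and
# within-60-um scalar summaries.

#' Pairwise correlations and distances within regions
#'
#' For every unordered pair of cells sharing a region label, the Pearson
#' correlation of their dF/F traces and the 3-D Euclidean distance between
#' their centroids (z from plane index times plane spacing when no
#' continuous z is available). Zero-variance traces are excluded from
#' pairing and counted.
#'
#' @param dff a [TraceMatrix()] (typically the 1 Hz dF/F of
#'   [spontaneousActivity()]).
#' @param rois optional [ROISet()] supplying positions and region labels;
#'   defaults to the metadata carried by `dff`.
#' @param region optional single region to restrict to.
#' @param planeSpacing axial plane spacing (um) used when z must be
#'   derived from the plane index.
#' @return data.frame with columns `i, j, region, distance, r`;
#'   `attr(, "nDropped")` counts zero-variance cells,
#'   `attr(, "flagged")` names regions with fewer than 2 usable cells.
#' @export
pairwiseCorrelations <- function(dff, rois = NULL, region = NULL,
                                 planeSpacing = 12) {
    stopifnot(is(dff, "TraceMatrix"))
    if (ncol(dff) < 3L) stop("need at least 3 timepoints")
    cells <- if (is.null(rois)) cellData(dff) else cellData(rois)
    need <- c("x", "y", "region")
    if (!all(need %in% colnames(cells)))
        stop("cell metadata must provide x, y and region")
    z <- if ("z" %in% colnames(cells)) cells$z
         else (cells$plane - 1) * planeSpacing
    vals <- traceValues(dff)
    regs <- if (is.null(region)) unique(cells$region) else region
    regs <- setdiff(regs, "unassigned")
    dropped <- 0L
    flagged <- character()
    out <- list()
    for (reg in regs) {
        idx <- which(cells$region == reg)
        v <- apply(vals[idx, , drop = FALSE], 1, sd)
        dropped <- dropped + sum(v == 0)
        idx <- idx[v > 0]
        if (length(idx) < 2L) { flagged <- c(flagged, reg); next }
        R <- cor(t(vals[idx, , drop = FALSE]))
        D <- as.matrix(dist(cbind(cells$x[idx], cells$y[idx], z[idx])))
        sel <- which(upper.tri(R), arr.ind = TRUE)
        out[[reg]] <- data.frame(
            i = idx[sel[, 1]], j = idx[sel[, 2]], region = reg,
            distance = D[upper.tri(D)], r = R[upper.tri(R)])
    }
    ans <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
           else data.frame(i = integer(), j = integer(),
                           region = character(), distance = numeric(),
                           r = numeric())
    attr(ans, "nDropped") <- dropped
    attr(ans, "flagged") <- flagged
    ans
}

#' Correlation-versus-distance profile
#'
#' Assigns pairs to half-open distance bins `[lo, hi)` and, within each
#' region and bin, averages positive and negative correlations
#' separately. The scalar summaries are the mean positive and mean
#' negative correlation over all pairs within `maxDistance`.
#'
#' @param pairs output of [pairwiseCorrelations()].
#' @param maxDistance distance cut-off for bins and summaries, um.
#' @param binWidth bin width, um.
#' @return A [CorrelationProfile][CorrelationProfile-class].
#' @export
correlationVsDistance <- function(pairs, maxDistance = 60, binWidth = 10) {
    if (binWidth <= 0) stop("binWidth must be positive")
    lo <- seq(0, maxDistance - binWidth, by = binWidth)
    hi <- lo + binWidth
    regs <- unique(pairs$region)
    bins <- list(); summ <- list()
    posMean <- function(r) if (any(r > 0)) mean(r[r > 0]) else NA_real_
    negMean <- function(r) if (any(r < 0)) mean(r[r < 0]) else NA_real_
    for (reg in c(regs, "all")) {
        sub <- if (reg == "all") pairs else pairs[pairs$region == reg, ]
        for (b in seq_along(lo)) {
            r <- sub$r[sub$distance >= lo[b] & sub$distance < hi[b]]
            bins[[length(bins) + 1L]] <- data.frame(
                region = reg, binLo = lo[b], binHi = hi[b],
                binCenter = (lo[b] + hi[b]) / 2,
                meanPositive = posMean(r), meanNegative = negMean(r),
                nPairs = length(r), nPositive = sum(r > 0),
                nNegative = sum(r < 0))
        }
        r60 <- sub$r[sub$distance <= maxDistance]
        summ[[length(summ) + 1L]] <- data.frame(
            region = reg, nPairs = length(r60),
            meanPositive = posMean(r60), meanNegative = negMean(r60),
            flagged = length(r60) == 0L)
    }
    new("CorrelationProfile",
        bins = do.call(rbind, c(bins, list(make.row.names = FALSE))),
        summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
        maxDistance = maxDistance,
        dropped = attr(pairs, "nDropped") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
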