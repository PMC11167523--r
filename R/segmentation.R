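# Nucleus detection by normalized cross-correlation against a bank of
# disc and annulus ("torus") templates, trace extraction over disc
# footprints, and mask-based brain-region assignment.

# Square template matrices for a filled disc and an annulus (inner radius
# half the outer) of the given outer radius.
.templateBank <- function(radii, annulusInner = 0.5) {
    bank <- list()
    for (r in radii) {
        w <- 2 * ceiling(r) + 1
        ctr <- ceiling(r) + 1
        d2 <- outer((seq_len(w) - ctr)^2, (seq_len(w) - ctr)^2, "+")
        disc <- (d2 <= r^2) * 1
        ann <- (d2 <= r^2 & d2 > (annulusInner * r)^2) * 1
        bank[[length(bank) + 1L]] <- list(shape = "disc", radius = r, t = disc)
        bank[[length(bank) + 1L]] <- list(shape = "annulus", radius = r, t = ann)
    }
    bank
}

# Normalized cross-correlation of a (zero-mean-normalized) template with
# every position of an image; windows with negligible variance score 0.
.nccMap <- function(img, tmpl) {
    t0 <- tmpl - mean(tmpl)
    denomT <- sqrt(sum(t0^2))
    if (denomT == 0) return(matrix(0, nrow(img), ncol(img)))
    ones <- matrix(1, nrow(tmpl), ncol(tmpl))
    nw <- length(tmpl)
    s1 <- EBImage::filter2(img, ones, boundary = "replicate")
    s2 <- EBImage::filter2(img^2, ones, boundary = "replicate")
    varI <- pmax(s2 - s1^2 / nw, 0)
    num <- EBImage::filter2(img, t0, boundary = "replicate")
    eps <- 1e-9 * (max(varI) + 1e-300)
    ans <- matrix(0, nrow(img), ncol(img))
    good <- varI > eps
    ans[good] <- num[good] / (sqrt(varI[good]) * denomT)
    ans
}

# TRUE where a pixel is >= all 8 neighbours (plateaus kept; NMS breaks ties).
.localMaxima <- function(s) {
    H <- nrow(s); W <- ncol(s)
    pad <- matrix(-Inf, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- s
    ok <- matrix(TRUE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        ok <- ok & s >= pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    }
    ok
}

#' Detect neuronal nuclei on a mean-intensity image
#'
#' Matches a bank of filled-disc and annulus templates (nuclear GCaMP
#' nuclei appear as bright discs or rings) against the image by normalized
#' cross-correlation, takes the per-pixel best match over the bank, and
#' keeps local maxima above `matchThreshold` after greedy non-maximum
#' suppression (descending score, ties broken in row-major pixel order).
#'
#' @param image numeric matrix, the mean-intensity image of one plane.
#' @param radii candidate nucleus radii in pixels.
#' @param matchThreshold minimum normalized cross-correlation score.
#' @param minSeparation minimum distance between accepted centroids, px.
#' @param minIntensity absolute brightness floor at the candidate centre
#'   (3x3-smoothed image). Normalized cross-correlation is contrast
#'   invariant, so a faint noise patch can match the template shape; the
#'   floor rejects such matches. Default `NULL` estimates it as
#'   `median + 3 * mad` of the image.
#' @param plane plane index recorded for the detections.
#' @param planeSpacing axial plane spacing, micrometres.
#' @param pxSize lateral pixel size, micrometres.
#' @return An [ROISet()]; `footprint` radius is the best-matching template
#'   radius and centroids are reported at the template centre.
#' @export
detectNuclei <- function(image, radii = 3:7, matchThreshold = 0.5,
                         minSeparation = 5, minIntensity = NULL,
                         plane = 1L, planeSpacing = 12, pxSize = 1) {
    if (!length(radii)) stop("radii must be non-empty")
    if (!all(is.finite(image))) stop("image must be finite")
    image <- as.matrix(image)
    if (is.null(minIntensity))
        minIntensity <- stats::median(image) + 3 * stats::mad(image)
    smooth <- EBImage::filter2(image, matrix(1 / 9, 3, 3),
                               boundary = "replicate")

    best <- matrix(-Inf, nrow(image), ncol(image))
    bestR <- matrix(NA_real_, nrow(image), ncol(image))
    for (tm in .templateBank(radii)) {
        sc <- .nccMap(image, tm$t)
        upd <- sc > best
        best[upd] <- sc[upd]
        bestR[upd] <- tm$radius
    }

    cand <- which(.localMaxima(best) & best > matchThreshold &
                  smooth >= minIntensity)
    empty <- DataFrame(id = integer(), x = numeric(), y = numeric(),
                       plane = integer(), z = numeric(), radius = numeric(),
                       score = numeric(), region = character())
    if (!length(cand)) return(ROISet(empty))
    ## greedy NMS: descending score, ties row-major (linear index)
    cand <- cand[order(-best[cand], cand)]
    rows <- ((cand - 1L) %% nrow(image)) + 1L
    cols <- ((cand - 1L) %/% nrow(image)) + 1L
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
        if (i == 1L) { keep[1L] <- TRUE; next }
        acc <- which(keep)
        d2 <- (rows[acc] - rows[i])^2 + (cols[acc] - cols[i])^2
        keep[i] <- min(d2) >= minSeparation^2
    }
    rows <- rows[keep]; cols <- cols[keep]; cand <- cand[keep]
    ROISet(DataFrame(
        id = seq_along(cand),
        x = (cols - 1) * pxSize,
        y = (rows - 1) * pxSize,
        plane = as.integer(rep(plane, length(cand))),
        z = rep((plane - 1) * planeSpacing, length(cand)),
        radius = bestR[cand],
        score = best[cand],
        region = rep("unassigned", length(cand))))
}

#' Extract per-cell traces from a movie
#'
#' For every cell the trace is the mean pixel intensity within its disc
#' footprint on its plane, one sample per volume. Footprints clipped by
#' the image edge are computed on the clipped pixel set and flagged.
#'
#' @param movie a [Movie()].
#' @param rois an [ROISet()].
#' @return A raw [TraceMatrix()] whose `rowData` carries the ROI table
#'   plus a logical `clipped` column.
#' @export
extractTraces <- function(movie, rois) {
    stopifnot(is(movie, "Movie"), is(rois, "ROISet"))
    cells <- rois@cells
    d <- dim(movie@frames)
    H <- d[3]; W <- d[4]; nT <- d[2]
    px <- .toPixel(cells$x, cells$y, movie@pxSize)
    vals <- matrix(NA_real_, nrow(cells), nT)
    clipped <- logical(nrow(cells))
    for (i in seq_len(nrow(cells))) {
        if (cells$plane[i] < 1L || cells$plane[i] > d[1])
            stop("ROI plane outside movie")
        off <- .discOffsets(cells$radius[i])
        rows <- px$row[i] + off$dr
        cols <- px$col[i] + off$dc
        keep <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
        if (!any(keep)) stop(sprintf("ROI %d fully outside image bounds", i))
        clipped[i] <- !all(keep)
        rows <- rows[keep]; cols <- cols[keep]
        acc <- numeric(nT)
        for (k in seq_along(rows))
            acc <- acc + movie@frames[cells$plane[i], , rows[k], cols[k]]
        vals[i, ] <- acc / length(rows)
    }
    cells$clipped <- clipped
    TraceMatrix(vals, volumeRate = movie@volumeRate, cells = cells,
                signal = "raw")
}

#' Assign cells to brain regions from label masks
#'
#' Looks up the mask label at each cell's centroid pixel on its plane;
#' label 0 maps to `"unassigned"`.
#'
#' @param rois an [ROISet()].
#' @param masks list of per-plane integer label matrices.
#' @param labels data.frame with columns `label`, `region`.
#' @param pxSize lateral pixel size, micrometres.
#' @return The [ROISet()] with `region` filled in; per-region counts are
#'   attached as `metadata(cellData(x))$regionCounts`.
#' @export
assignRegions <- function(rois, masks, labels, pxSize = 1) {
    stopifnot(is(rois, "ROISet"))
    cells <- rois@cells
    planes <- unique(cells$plane)
    if (any(planes > length(masks)) || any(vapply(masks[planes], is.null,
                                                  logical(1))))
        stop("missing mask for plane ",
             paste(planes[planes > length(masks)], collapse = ", "))
    px <- .toPixel(cells$x, cells$y, pxSize)
    region <- character(nrow(cells))
    for (i in seq_len(nrow(cells))) {
        m <- masks[[cells$plane[i]]]
        lab <- if (px$row[i] >= 1 && px$row[i] <= nrow(m) &&
                   px$col[i] >= 1 && px$col[i] <= ncol(m))
                   m[px$row[i], px$col[i]] else 0L
        region[i] <- if (lab == 0L) "unassigned"
                     else labels$region[match(lab, labels$label)]
    }
    cells$region <- region
    counts <- table(region)
    out <- ROISet(cells)
    S4Vectors::metadata(out@cells)$regionCounts <-
        setNames(as.integer(counts), names(counts))
    out
}

#' Segment a movie end to end
#'
#' Convenience wrapper: per-plane mean image, nucleus detection, optional
#' region assignment, trace extraction.
#'
#' @inheritParams detectNuclei
#' @param movie a [Movie()].
#' @param masks,labels optional region label masks (see [assignRegions()]).
#' @return List with `rois` (an [ROISet()]) and `traces` (a
#'   [TraceMatrix()]).
#' @export
segmentMovie <- function(movie, radii = 3:7, matchThreshold = 0.5,
                         minSeparation = 5, minIntensity = NULL,
                         masks = NULL, labels = NULL) {
    stopifnot(is(movie, "Movie"))
    nPlanes <- dim(movie@frames)[1]
    sets <- lapply(seq_len(nPlanes), function(p)
        detectNuclei(meanImage(movie, p), radii = radii,
                     matchThreshold = matchThreshold,
                     minSeparation = minSeparation,
                     minIntensity = minIntensity, plane = p,
                     planeSpacing = movie@planeSpacing,
                     pxSize = movie@pxSize)@cells)
    cells <- do.call(rbind, sets)
    if (nrow(cells)) cells$id <- seq_len(nrow(cells))
    rois <- ROISet(cells)
    if (!is.null(masks))
        rois <- assignRegions(rois, masks, labels, pxSize = movie@pxSize)
    list(rois = rois,
         traces = if (nrow(cells)) extractTraces(movie, rois) else NULL)
}
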