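# Image-domain fixture generation: nuclei rendered as flat discs whose
# intensity follows the cell's trace, plus matching region label masks.
# Render and extraction share .discOffsets so a zero-noise round trip is
# exact.

# Integer pixel offsets (dr, dc) of a filled disc of the given radius.
.discOffsets <- function(radius) {
    r <- ceiling(radius)
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Centroid (x, y in um) -> nearest 1-based pixel (row, col).
.toPixel <- function(x, y, pxSize) {
    list(row = as.integer(round(y / pxSize)) + 1L,
         col = as.integer(round(x / pxSize)) + 1L)
}

#' Per-plane brain-region label masks
#'
#' Rasterizes the configured region bounding boxes into per-plane integer
#' label images (0 = unlabelled background) plus a label table.
#'
#' @param config a [SimulationConfig][simulationConfig()].
#' @return List with `masks` (list of height x width integer matrices, one
#'   per plane) and `labels` (data.frame with columns `label`, `region`).
#' @export
regionMasks <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    W <- config@frameSize[1]; H <- config@frameSize[2]
    geo <- config@regionGeometry
    px <- config@pxSize
    masks <- lapply(seq_len(config@planeCount), function(p) {
        z <- (p - 1) * config@planeSpacing
        m <- matrix(0L, H, W)
        for (i in seq_len(nrow(geo))) {
            if (z < geo$z0[i] || z > geo$z1[i]) next
            rows <- which((seq_len(H) - 1) * px >= geo$y0[i] &
                          (seq_len(H) - 1) * px <= geo$y1[i])
            cols <- which((seq_len(W) - 1) * px >= geo$x0[i] &
                          (seq_len(W) - 1) * px <= geo$x1[i])
            m[rows, cols] <- i
        }
        m
    })
    list(masks = masks,
         labels = data.frame(label = seq_len(nrow(geo)), region = geo$region))
}

#' Render a simulated recording as a multi-plane movie
#'
#' Draws each cell on its nearest imaging plane as a flat disc of radius
#' `config@nucleusRadius` whose intensity follows the cell's raw trace;
#' overlapping discs add. Additive Gaussian pixel noise is controlled by
#' `config@pixelNoiseSd`. The matching region label masks are returned
#' alongside the movie.
#'
#' @param traces a raw [TraceMatrix()] from [simulateTraces()].
#' @param truth the matching `GroundTruth`.
#' @param config the [SimulationConfig][simulationConfig()] used for the
#'   simulation (frame geometry is taken from here).
#' @param maxOverlapFraction warn when more than this fraction of cells
#'   share at least one pixel with another cell.
#' @return List with `movie` (a [Movie()]), `masks` and `labels` (as
#'   [regionMasks()]).
#' @export
renderMovie <- function(traces, truth, config, maxOverlapFraction = 0) {
    stopifnot(is(traces, "TraceMatrix"), is(truth, "GroundTruth"),
              is(config, "SimulationConfig"))
    if (signalType(traces) != "raw")
        stop("renderMovie expects raw fluorescence traces")
    W <- config@frameSize[1]; H <- config@frameSize[2]
    cells <- truth@cells
    n <- nrow(cells)
    nT <- ncol(traces)
    vals <- traceValues(traces)
    px <- .toPixel(cells$x, cells$y, config@pxSize)
    if (any(px$row < 1L | px$row > H | px$col < 1L | px$col > W))
        stop("cell centroid outside frame bounds")

    off <- .discOffsets(config@nucleusRadius)
    frames <- array(0, dim = c(config@planeCount, nT, H, W))
    occupancy <- array(0L, dim = c(config@planeCount, H, W))
    for (i in seq_len(n)) {
        p <- cells$plane[i]
        rows <- px$row[i] + off$dr
        cols <- px$col[i] + off$dc
        keep <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
        rows <- rows[keep]; cols <- cols[keep]
        for (k in seq_along(rows)) {
            frames[p, , rows[k], cols[k]] <-
                frames[p, , rows[k], cols[k]] + vals[i, ]
            occupancy[p, rows[k], cols[k]] <-
                occupancy[p, rows[k], cols[k]] + 1L
        }
    }
    overlapped <- vapply(seq_len(n), function(i) {
        p <- cells$plane[i]
        rows <- px$row[i] + off$dr
        cols <- px$col[i] + off$dc
        keep <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
        any(occupancy[cbind(p, rows[keep], cols[keep])] > 1L)
    }, logical(1))
    if (mean(overlapped) > maxOverlapFraction)
        warning(sprintf("%d of %d rendered nuclei overlap a neighbour",
                        sum(overlapped), n))
    if (config@pixelNoiseSd > 0) {
        set.seed(config@seed)    # render noise reproducible per config
        frames <- frames + array(rnorm(length(frames),
                                       sd = config@pixelNoiseSd),
                                 dim = dim(frames))
    }
    rm <- regionMasks(config)
    list(movie = Movie(frames, volumeRate = volumeRate(traces),
                       planeSpacing = config@planeSpacing,
                       pxSize = config@pxSize),
         masks = rm$masks, labels = rm$labels)
}

#' Mean-intensity image of one plane
#'
#' @param movie a [Movie()].
#' @param plane plane index.
#' @return height x width matrix, the temporal mean of that plane.
#' @export
meanImage <- function(movie, plane = 1L) {
    stopifnot(is(movie, "Movie"))
    d <- dim(movie@frames)
    if (plane < 1L || plane > d[1]) stop("plane out of range")
    if (d[2] == 1L) return(movie@frames[plane, 1, , ])
    apply(movie@frames[plane, , , , drop = FALSE], c(3, 4), mean)
}
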