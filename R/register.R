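# Rigid per-plane motion correction: integer translation of every frame
# onto the plane's mean image, estimated by FFT cross-correlation.

# Integer (dy, dx) such that shifting `frame` by (-dy, -dx) best aligns it
# with `ref` (cyclic cross-correlation peak).
.estimateShift <- function(ref, frame) {
    a <- ref - mean(ref)
    b <- frame - mean(frame)
    cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
    pk <- which.max(cc)
    H <- nrow(ref); W <- ncol(ref)
    dy <- ((pk - 1) %% H)
    dx <- ((pk - 1) %/% H)
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    c(dy = -dy, dx = -dx)
}

# Translate a matrix by (dy, dx) with edge replication.
.translate <- function(m, dy, dx) {
    H <- nrow(m); W <- ncol(m)
    rows <- pmin(pmax(seq_len(H) - dy, 1L), H)
    cols <- pmin(pmax(seq_len(W) - dx, 1L), W)
    m[rows, cols, drop = FALSE]
}

#' Rigid motion correction of a multi-plane movie
#'
#' Estimates, per plane, an integer translation of every frame onto the
#' plane's mean image by cross-correlation and applies the inverse shift
#' (edge pixels replicated). Shifts larger than `maxShift` are clamped and
#' the frame flagged.
#'
#' @param movie a [Movie()] with at least two frames per plane.
#' @param maxShift maximum trusted shift, pixels.
#' @return List with `movie` (motion-corrected) and `shifts` (data.frame
#'   with columns `plane, frame, dy, dx, clamped`).
#' @export
registerFrames <- function(movie, maxShift = 10) {
    stopifnot(is(movie, "Movie"))
    d <- dim(movie@frames)
    if (d[2] < 2L) stop("registration needs at least 2 frames per plane")
    out <- movie@frames
    log <- vector("list", d[1])
    for (p in seq_len(d[1])) {
        ref <- meanImage(movie, p)
        dys <- integer(d[2]); dxs <- integer(d[2]); clamped <- logical(d[2])
        for (t in seq_len(d[2])) {
            sh <- .estimateShift(ref, movie@frames[p, t, , ])
            cl <- abs(sh) > maxShift
            if (any(cl)) {
                warning(sprintf(
                    "plane %d frame %d: shift (%d, %d) exceeds maxShift %d; clamped",
                    p, t, sh[1], sh[2], maxShift))
                sh <- pmin(pmax(sh, -maxShift), maxShift)
                clamped[t] <- TRUE
            }
            dys[t] <- sh[1]; dxs[t] <- sh[2]
            if (sh[1] != 0L || sh[2] != 0L)
                out[p, t, , ] <- .translate(movie@frames[p, t, , ],
                                            -sh[1], -sh[2])
        }
        log[[p]] <- data.frame(plane = p, frame = seq_len(d[2]),
                               dy = dys, dx = dxs, clamped = clamped)
    }
    list(movie = Movie(out, volumeRate = movie@volumeRate,
                       planeSpacing = movie@planeSpacing,
                       pxSize = movie@pxSize),
         shifts = do.call(rbind, log))
}
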