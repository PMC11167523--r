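# File interfaces: multi-page TIFF movies with a YAML calibration
# sidecar, per-plane label masks, delimited ROI/trace/schedule/ERG
# tables, and a JSON run report. TIFF stores values scaled to [0, 1];
# the scale factor lives in the sidecar so reading restores intensities.

#' Write a movie as multi-page TIFF plus metadata sidecar
#'
#' Pages are ordered plane-major (all volumes of plane 1, then plane 2,
#' ...). Intensities are scaled into [0, 1] for storage; the scale and
#' calibration are recorded in `<path>.yaml`.
#'
#' @param movie a [Movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path) {
    stopifnot(is(movie, "Movie"))
    d <- dim(movie@frames)
    sc <- max(movie@frames, 1e-12)
    pages <- list()
    for (p in seq_len(d[1])) for (t in seq_len(d[2]))
        pages[[length(pages) + 1L]] <- movie@frames[p, t, , ] / sc
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                    compression = "deflate")
    yaml::write_yaml(list(
        planes = d[1], volumes = d[2], height = d[3], width = d[4],
        volume_rate = movie@volumeRate, plane_spacing = movie@planeSpacing,
        px_size = movie@pxSize, intensity_scale = sc,
        page_order = "plane-major"), paste0(path, ".yaml"))
    invisible(path)
}

#' Read a movie written by [writeMovie()]
#'
#' @param path TIFF path (sidecar expected at `<path>.yaml`).
#' @return A [Movie()].
#' @export
readMovie <- function(path) {
    meta <- yaml::read_yaml(paste0(path, ".yaml"))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    frames <- array(0, dim = c(meta$planes, meta$volumes,
                               meta$height, meta$width))
    i <- 1L
    for (p in seq_len(meta$planes)) for (t in seq_len(meta$volumes)) {
        frames[p, t, , ] <- pages[[i]] * meta$intensity_scale
        i <- i + 1L
    }
    Movie(frames, volumeRate = meta$volume_rate,
          planeSpacing = meta$plane_spacing, pxSize = meta$px_size)
}

#' Write / read per-plane region label masks
#'
#' One 8-bit TIFF per plane (`mask_plane<k>.tif`, labels as integer pixel
#' values) and a `labels.tsv` table mapping labels to region names.
#'
#' @param masks list of integer label matrices, one per plane.
#' @param labels data.frame with columns `label`, `region`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a list with `masks` and `labels` (read).
#' @export
writeMasks <- function(masks, labels, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (p in seq_along(masks))
        tiff::writeTIFF(masks[[p]] / 255,
                        file.path(dir, sprintf("mask_plane%02d.tif", p)),
                        bits.per.sample = 8L, reduce = FALSE)
    write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeMasks
#' @export
readMasks <- function(dir) {
    files <- sort(list.files(dir, pattern = "^mask_plane[0-9]+\\.tif$",
                             full.names = TRUE))
    masks <- lapply(files, function(f) {
        m <- tiff::readTIFF(f)
        matrix(as.integer(round(m * 255)), nrow = nrow(m))
    })
    labels <- read.delim(file.path(dir, "labels.tsv"))
    list(masks = masks, labels = labels)
}

#' Write / read an ROI table
#'
#' Tab-delimited: one row per cell with id, centroid, plane, radius and
#' region.
#'
#' @param rois an [ROISet()].
#' @param path output TSV path.
#' @return `path` (write) or an [ROISet()] (read).
#' @export
writeROISet <- function(rois, path) {
    stopifnot(is(rois, "ROISet"))
    write.table(as.data.frame(rois@cells), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeROISet
#' @export
readROISet <- function(path) {
    ROISet(read.delim(path))
}

#' Write / read a trace matrix
#'
#' Traces go to `<prefix>_traces.tsv` (cells x timepoints), per-cell
#' metadata to `<prefix>_cells.tsv`, and the calibration to
#' `<prefix>_meta.yaml`.
#'
#' @param traces a [TraceMatrix()].
#' @param prefix output path prefix.
#' @return `prefix` (write) or a [TraceMatrix()] (read).
#' @export
writeTraceMatrix <- function(traces, prefix) {
    stopifnot(is(traces, "TraceMatrix"))
    write.table(traceValues(traces), paste0(prefix, "_traces.tsv"),
                sep = "\t", quote = FALSE, col.names = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(cellData(traces))
    if (ncol(cd))
        write.table(cd, paste0(prefix, "_cells.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(volume_rate = volumeRate(traces),
                          signal = signalType(traces)),
                     paste0(prefix, "_meta.yaml"))
    invisible(prefix)
}

#' @rdname writeTraceMatrix
#' @export
readTraceMatrix <- function(prefix) {
    meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
    vals <- as.matrix(read.delim(paste0(prefix, "_traces.tsv"),
                                 header = FALSE))
    dimnames(vals) <- NULL
    cellsFile <- paste0(prefix, "_cells.tsv")
    cells <- if (file.exists(cellsFile)) read.delim(cellsFile) else NULL
    TraceMatrix(vals, volumeRate = meta$volume_rate, cells = cells,
                signal = meta$signal)
}

#' Write / read a stimulus schedule
#'
#' Tab-delimited onset/offset seconds.
#'
#' @param schedule a [StimulusSchedule()].
#' @param path TSV path.
#' @return `path` (write) or a [StimulusSchedule()] (read).
#' @export
writeStimulusSchedule <- function(schedule, path) {
    stopifnot(is(schedule, "StimulusSchedule"))
    write.table(data.frame(onset = schedule@onsets,
                           offset = schedule@offsets),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeStimulusSchedule
#' @export
readStimulusSchedule <- function(path) {
    d <- read.delim(path)
    StimulusSchedule(d$onset, d$offset)
}

#' Read an ERG voltage trace from delimited text
#'
#' Accepts a one-column file of voltages or a two-column `time  voltage`
#' file (time ignored; the sample rate is taken from the arguments).
#'
#' @param path delimited text file.
#' @param sampleRate digitization rate, Hz.
#' @param stimOnsets stimulus onset times, seconds.
#' @param stimDuration stimulus duration, seconds.
#' @return An [ERGRecording()].
#' @export
readERG <- function(path, sampleRate, stimOnsets, stimDuration = 1) {
    d <- read.delim(path, header = FALSE)
    v <- d[[ncol(d)]]
    ERGRecording(v, sampleRate = sampleRate, stimOnsets = stimOnsets,
                 stimDuration = stimDuration)
}

#' Write a structured run report
#'
#' JSON report of configuration, seeds and result tables, for audit
#' trails of analysis runs.
#'
#' @param report a named list (data.frames allowed).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    invisible(path)
}

#' Write group-comparison tables
#'
#' One row per comparison: metric, group sizes, means, SDs, rank-sum
#' statistic, p-value, stars and the method used.
#'
#' @param comparisons list of
#'   [GroupComparison][GroupComparison-class] objects.
#' @param path output TSV path.
#' @return The assembled data.frame, invisibly.
#' @export
writeComparisonTable <- function(comparisons, path) {
    if (is(comparisons, "GroupComparison")) comparisons <- list(comparisons)
    tab <- do.call(rbind, lapply(comparisons, function(x) data.frame(
        metric = x@metric,
        nA = length(x@groupA), nB = length(x@groupB),
        meanA = mean(x@groupA), sdA = sd(x@groupA),
        meanB = mean(x@groupB), sdB = sd(x@groupB),
        W = x@statistic, p = x@pValue, stars = x@stars,
        method = x@method)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(tab)
}
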