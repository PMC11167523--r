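#' Accessors for the core containers
#'
#' Small accessor generics so that slots are never reached into directly:
#' sampling rates, time axes, the trace matrix, per-cell metadata and
#' schedule times.
#'
#' @param x one of the package's S4 objects.
#' @return The corresponding component (see the individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeRate", function(x) standardGeneric("volumeRate"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("signalType", function(x) standardGeneric("signalType"))

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
setMethod("volumeRate", "TraceMatrix", function(x) metadata(x)$volumeRate)

#' @rdname accessors
setMethod("volumeRate", "Movie", function(x) x@volumeRate)

#' @rdname accessors
setMethod("timeAxis", "TraceMatrix", function(x)
    (seq_len(ncol(x)) - 1) / volumeRate(x))

#' @rdname accessors
setMethod("timeAxis", "ERGRecording", function(x)
    (seq_along(x@voltage) - 1) / x@sampleRate)

#' @rdname accessors
setMethod("traceValues", "TraceMatrix", function(x) assay(x))

#' @rdname accessors
setMethod("signalType", "TraceMatrix", function(x) metadata(x)$signal)

#' @rdname accessors
setMethod("cellData", "TraceMatrix", function(x) rowData(x))

#' @rdname accessors
setMethod("cellData", "ROISet", function(x) x@cells)

#' @rdname accessors
setMethod("cellData", "GroundTruth", function(x) x@cells)

#' @rdname accessors
setMethod("cellData", "EvokedResult", function(x) x@cells)

#' @rdname accessors
setMethod("cellData", "ActivityMetrics", function(x) x@cells)

#' @rdname accessors
setMethod("onsets", "StimulusSchedule", function(x) x@onsets)

#' @rdname accessors
setMethod("offsets", "StimulusSchedule", function(x) x@offsets)

#' @rdname accessors
setMethod("onsets", "ERGRecording", function(x) x@stimOnsets)

#' @rdname accessors
setMethod("sampleRate", "ERGRecording", function(x) x@sampleRate)

#' @rdname accessors
setMethod("regionTable", "EvokedResult", function(x) x@regions)

#' @rdname accessors
setMethod("regionTable", "ActivityMetrics", function(x) x@regions)

#' @rdname accessors
setMethod("regionTable", "CorrelationProfile", function(x) x@summary)

#' Spike log of a simulated recording
#'
#' Ground-truth spike times (seconds) of each simulated cell.
#'
#' @param x a `GroundTruth`.
#' @return A list, one numeric vector of spike times per cell.
#' @export
spikeTimes <- function(x) {
    stopifnot(is(x, "GroundTruth"))
    x@spikes
}

#' Movie frame accessor
#'
#' @param x a `Movie`.
#' @param plane plane index (1-based).
#' @param time volume index (1-based); omit for all volumes of the plane.
#' @return A height x width matrix (single volume) or time x height x width
#'   array.
#' @export
movieFrame <- function(x, plane, time = NULL) {
    stopifnot(is(x, "Movie"))
    if (is.null(time)) x@frames[plane, , , , drop = TRUE]
    else x@frames[plane, time, , , drop = TRUE]
}
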