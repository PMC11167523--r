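# Small configurations shared across tests. Durations are kept short;
# evoked tests use a compact custom protocol instead of the full 40-min
# recording.

tinyConfig <- function(...) {
    simulationConfig(nCells = 10, duration = 60,
                     evokedFractions = c(0, 0, 0), seed = 1, ...)
}

# Compact evoked protocol: five 20-s stimuli in a 300-s recording.
shortSchedule <- function() {
    StimulusSchedule(onsets = c(50, 100, 150, 200, 250),
                     offsets = c(70, 120, 170, 220, 270))
}

# Match detections to ground truth within `tol` px; returns counts.
matchDetections <- function(det, truthCells, tol = 3) {
    d <- cellData(det)
    if (nrow(d) == 0L)
        return(list(tp = 0L, fp = 0L, fn = nrow(truthCells), err = numeric()))
    D <- sqrt(outer(d$x, truthCells$x, "-")^2 +
              outer(d$y, truthCells$y, "-")^2)
    matched <- apply(D, 2, min) <= tol
    list(tp = sum(matched), fp = sum(apply(D, 1, min) > tol),
         fn = sum(!matched), err = apply(D, 2, min)[matched])
}

# Brute-force percentile with linear interpolation between order
# statistics (independent oracle for the rolling baseline).
bruteQuantile <- function(x, prob) {
    x <- sort(x)
    h <- (length(x) - 1) * prob
    k <- floor(h)
    g <- h - k
    q <- x[k + 1]
    if (g > 0 && k + 2 <= length(x)) q <- q + g * (x[k + 2] - q)
    q
}
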