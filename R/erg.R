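# Electroretinogram: synthetic b-wave trains, per-stimulus baseline
# normalization, train averaging and the 0-200 ms ON-response amplitude.

# Difference-of-exponentials b-wave kernel on the recording's sample
# grid, scaled so that its mean over [0, window) seconds equals 1.
.bwaveKernel <- function(sampleRate, riseTau = 0.02, decayTau = 0.08,
                         span = 1, window = 0.2) {
    t <- seq(0, span, by = 1 / sampleRate)
    t <- t[t < span]
    k <- exp(-t / decayTau) - exp(-t / riseTau)
    k / mean(k[t < window])
}

#' Simulate an ERG recording with a b-wave train
#'
#' A voltage trace containing `nStimuli` light stimuli (the train starts
#' at `trainStart` seconds; each stimulus lasts `stimDuration` seconds
#' with `interval` seconds between stimuli). Each stimulus adds a b-wave
#' transient modelled as a difference of exponentials peaking within
#' 0-200 ms of onset, scaled so that its mean over the first 200 ms
#' equals `amplitude`; Gaussian noise is added on top. The ground-truth
#' amplitude is recorded in the returned object.
#'
#' @param amplitude ground-truth 0-200 ms mean ON-response amplitude, uV.
#' @param noiseSd additive Gaussian noise SD, uV.
#' @param nStimuli number of stimuli in the train.
#' @param stimDuration stimulus duration, seconds.
#' @param interval gap between consecutive stimuli, seconds.
#' @param sampleRate digitization rate, Hz (at least 1 kHz).
#' @param trainStart onset of the first stimulus, seconds.
#' @param duration total record duration, seconds (default: one stimulus
#'   span past the last onset).
#' @param riseTau,decayTau b-wave kernel time constants, seconds.
#' @param seed RNG seed.
#' @return An [ERGRecording()].
#' @examples
#' rec <- simulateERG(amplitude = 20, noiseSd = 0)
#' onsets(rec)    # 5, 11, ..., 59 s
#' @export
simulateERG <- function(amplitude, noiseSd = 0, nStimuli = 10L,
                        stimDuration = 1, interval = 5,
                        sampleRate = 10000, trainStart = 5,
                        duration = NULL, riseTau = 0.02, decayTau = 0.08,
                        seed = 1L) {
    if (stimDuration < 0 || interval < 0 || trainStart < 0)
        stop("durations and intervals must be non-negative")
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    if (sampleRate < 1000) stop("sampleRate must be at least 1 kHz")
    stimOnsets <- trainStart +
        (seq_len(nStimuli) - 1) * (stimDuration + interval)
    if (is.null(duration))
        duration <- max(stimOnsets) + max(stimDuration, 1)
    nSamples <- round(duration * sampleRate)
    v <- numeric(nSamples)
    kernel <- amplitude * .bwaveKernel(sampleRate, riseTau, decayTau)
    for (on in stimOnsets) {
        i0 <- round(on * sampleRate) + 1L
        idx <- i0:min(i0 + length(kernel) - 1L, nSamples)
        v[idx] <- v[idx] + kernel[seq_along(idx)]
    }
    set.seed(seed)
    if (noiseSd > 0) v <- v + rnorm(nSamples, sd = noiseSd)
    ERGRecording(v, sampleRate = sampleRate, stimOnsets = stimOnsets,
                 stimDuration = stimDuration, trueAmplitude = amplitude)
}

#' Baseline-normalize and average the stimulus train
#'
#' Each stimulus segment (from `baseline` seconds before onset to `span`
#' seconds after) has the mean of its pre-onset baseline window
#' subtracted; the baseline-subtracted segments are then averaged aligned
#' on onset.
#'
#' @param rec an [ERGRecording()].
#' @param baseline pre-onset baseline window, seconds.
#' @param span post-onset segment span, seconds.
#' @return List with `response` (averaged voltage), `time` (seconds
#'   relative to onset) and `nStimuli`.
#' @export
normalizeAndAverage <- function(rec, baseline = 0.2, span = 1) {
    stopifnot(is(rec, "ERGRecording"))
    sr <- rec@sampleRate
    nb <- round(baseline * sr)
    ns <- round(span * sr)
    nV <- length(rec@voltage)
    acc <- numeric(nb + ns)
    for (k in seq_along(rec@stimOnsets)) {
        i0 <- round(rec@stimOnsets[k] * sr) + 1L
        idx <- (i0 - nb):(i0 + ns - 1L)
        if (idx[1] < 1L)
            stop(sprintf(
                "stimulus %d lacks %g s of pre-onset data", k, baseline))
        if (idx[length(idx)] > nV)
            stop(sprintf("stimulus %d segment exceeds the recording", k))
        seg <- rec@voltage[idx]
        acc <- acc + (seg - mean(seg[seq_len(nb)]))
    }
    list(response = acc / length(rec@stimOnsets),
         time = ((seq_len(nb + ns) - 1L) - nb) / sr,
         nStimuli = length(rec@stimOnsets))
}

#' Mean ON-response amplitude
#'
#' Mean of the averaged, baseline-subtracted response over the window
#' after light onset (0-200 ms by default), the b-wave quantification.
#'
#' @param avg output of [normalizeAndAverage()].
#' @param window two numbers, window after onset in seconds.
#' @return Scalar amplitude in the units of the voltage trace.
#' @export
onResponseAmplitude <- function(avg, window = c(0, 0.2)) {
    sel <- avg$time >= window[1] & avg$time < window[2]
    if (!any(sel)) stop("amplitude window outside the averaged segment")
    mean(avg$response[sel])
}

#' ERG amplitude pipeline
#'
#' Baseline normalization, train averaging and the 0-200 ms mean
#' amplitude in one call.
#'
#' @inheritParams normalizeAndAverage
#' @return Scalar ON-response amplitude.
#' @export
ergAmplitude <- function(rec, baseline = 0.2, span = 1) {
    onResponseAmplitude(normalizeAndAverage(rec, baseline, span))
}
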