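---
title: "Models and methods behind zfBrainActivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zfBrainActivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters and the
numerical conventions of the package, and states which design choices
were genuinely open and how they were resolved.

# The recording model

The pipeline targets volumetric two-photon recordings of larval
zebrafish expressing nuclear GCaMP6s in all differentiated neurons:
8 planes per volume at 3.86 volumes/s, 40-minute sessions consisting of
10 minutes of darkness followed by five 60-s whole-field light stimuli
with onsets at minutes 10, 15, 20, 25 and 30, and four analysed brain
parcels (telencephalon, habenula, optic tectum/thalamus, hindbrain).
The effective per-cell sampling rate is the volume rate, so nuclear
indicator kinetics (seconds) are well resolved while spikes are not —
every statistic here is defined on fluorescence, not on inferred spikes.

# The synthetic-data generator

`simulateTraces()` is a forward model of such recordings with known
ground truth. For cell $i$ with baseline fluorescence $f_{0,i}$:

$$F_i(t) = f_{0,i}\bigl(1 + A\,c_i(t) + \lambda L_i(t) + e_i(t) + b_i(t)\bigr)
  + \varepsilon_i(t)$$

* **Spiking and calcium.** Spikes are a homogeneous Poisson process
  (default 1 Hz); $c_i$ is the spike count sequence filtered by a
  single-exponential kernel with decay $\tau$ = 3.5 s. Nuclear GCaMP6s
  is a slow indicator; no kinetics are published for these recordings,
  so $\tau$ is a configurable stand-in chosen at the slow end of the
  GCaMP6s range. The per-spike amplitude $A$ defaults to 0.15 dF/F.
* **Shared latent drive.** $L$ is a zero-mean unit-variance Gaussian
  field, white in time, with spatial covariance
  $\mathrm{Cor}(L_i, L_j) = e^{-d_{ij}/\ell}$ (Cholesky factorisation of
  the cross-cell kernel; $\ell$ defaults to 20 µm). $\lambda$ is the
  latent amplitude in dF/F units; the shared *fraction* of variance
  follows as $\lambda^2 / (A^2\,\mathrm{Var}(c) + \lambda^2 +
  \sigma^2)$. The default $\lambda = 0.2$ was calibrated once so that
  within-60-µm mean pairwise correlations land in the 0.1–0.2 range
  reported for control fish in this preparation, and is not revisited.
* **Evoked classes.** Per region, fixed fractions of cells (defaults
  30 % / 10 % / 10 %) are ON-activated (add `evokedAmplitude`, default
  0.5 dF/F, while the light is on), OFF-activated (same amplitude for
  10 s after light offset), or inhibited (spike rate multiplied by 0.1
  during the stimulus). Inhibition is modelled as rate suppression, so
  the negative dF/F deflection the classifier must find emerges from the
  loss of ongoing calcium, not from an artificial negative transient;
  the default spike rate and amplitude make that deflection clearly
  exceed twice the trial-averaged baseline SD.
* **Planted activity bursts.** For spontaneous-activity recovery, each
  cell can be given a target active fraction. Bursts of amplitude 5
  dF/F switch state only on the 1-s grid of the recording clock, cycling
  with an integer period (default 25 s), so attainable fractions are
  multiples of 1/25 and the planted fraction is realized exactly; the
  off-seconds in every cycle keep the moving 8th-percentile baseline
  anchored at $f_0$ (fractions above ~0.9 would defeat it and warn).
* **Noise and geometry.** White Gaussian noise with sd
  `noiseSd`·$f_0$ (default 10 %). Cells are placed uniformly in
  per-region boxes with an 8-µm minimum separation; plane spacing is
  12 µm. Neither density nor noise level is published for the raw data;
  both are configurable stand-ins.

Because the latent drive is the only component shared between cells,
the expected Pearson correlation between two traces is available in
closed form (`analyticCorrelation()`), which is what the correlation
recovery tests compare against.

`renderMovie()` rasterises each cell on its nearest plane as a flat
disc (radius 4 px at 1 µm/px) whose intensity follows the raw trace;
rendering and trace extraction share the same pixel discretisation, so
a zero-noise render/extract round trip is exact. Default fixture frames
are 512 × 256 px (the instruments record 1536 × 512; full size adds
nothing to the tests). `simulateERG()` models the b-wave as a
difference of exponentials (rise 20 ms, decay 80 ms, peak at 37 ms)
scaled so its mean over 0–200 ms equals the requested amplitude — the
downstream amplitude estimate is then exact by construction at zero
noise.

# Analysis conventions

* **Detection.** Normalized cross-correlation against filled discs and
  annuli (inner radius half the outer) over radii 3–7 px; per-pixel
  best match over the bank; local maxima above 0.5 with greedy
  non-maximum suppression (descending score, ties in row-major order).
  Because NCC is contrast-invariant, candidates must additionally
  exceed a brightness floor (default: image median + 3 MAD) — without
  it, pure-noise patches in empty background match the template shape.
  Centroids are reported at the template centre, 0-based pixels;
  $z = (\text{plane} - 1) \times$ plane spacing.
* **Traces.** Mean pixel intensity over the disc footprint per volume.
  The trace statistic is a package decision (the source analyses do not
  state one); mean-over-disc is linear, which the tests exploit.
* **Evoked windows.** Baseline = 5 s before onset; response = 10 s
  after onset (ON) or offset (OFF); windows are converted to whole
  volumes by flooring the onset and ceiling the end. The baseline SD is
  computed on the *trial-averaged* dF/F pre-window, since
  classification follows trial averaging; the same pre-onset baseline
  serves the OFF window. "Inhibited" means amplitude below −2·SD,
  symmetric to activation. A zero-SD baseline with nonzero amplitude
  (noiseless degenerate input) classifies by sign and is flagged.
* **Spontaneous activity.** Ongoing window = volumes 460–2304
  (1-based, 1845 volumes ≈ 478 s at 3.86 Hz; the printed frame indices
  are authoritative, and the package surfaces the duration rather than
  second-guessing them). Moving-window length for the 8th-percentile
  baseline is not published; default 30 s, truncated at the edges.
  Percentiles interpolate linearly between order statistics, and the
  unit tests check every window against a brute-force sort-and-index
  oracle. The activity threshold "4 × the 8th percentile" is read as
  $F(t) > 4B(t)$ — the moving baseline is the only 8th-percentile
  quantity defined — equivalent to dF/F > 3. Resampling to 1 Hz is
  linear interpolation at integer seconds (deterministic and alias-safe
  for a slow nuclear indicator).
* **Correlations.** Computed on the 1-Hz dF/F (keeps pair counts and
  runtimes proportionate and matches the activity clock; the full-rate
  matrix can be passed instead). Bins are half-open, 10 µm wide, up to
  60 µm; positive and negative correlations are averaged separately
  (sign-restricted means — the source figures show positive and
  negative branches, and a signed mean would cancel them). Zero-variance
  traces are excluded and counted. 3-D distance uses the plane-derived
  z by default.
* **Wilcoxon rank-sum.** Midranks for ties; exact two-sided p by full
  enumeration (doubling the smaller tail, capped at 1) when
  $n_A + n_B \le 12$ with no ties, otherwise the normal approximation
  with tie and continuity correction; the method used is reported. The
  approximation is bit-identical to `stats::wilcox.test`; its worst-case
  deviation from the exact tail at $n_A = n_B = 7$ is 0.0124, in the
  p ≈ 0.45 region where it is inconsequential. Per-fish summary values
  are the unit of analysis. k for the display k-means sort is not
  published; default 10, seeding k-means++-style, and the ordering never
  feeds statistics.
* **ERG.** One trace per larva is analysed as given (no subjective
  "most representative" selection — that is not reproducible); hardware
  filtering is treated as a property of the input. The amplitude is the
  *mean* over 0–200 ms, matching the phrase "average voltage responses";
  a peak measure would be the main alternative and is not used.

# What the tests do and do not show

All recovery tests run on the generator, which emulates Poisson
spiking, indicator filtering, distance-dependent shared drive,
stimulus-locked responses and white noise — but not motion artefacts
beyond rigid translation, bleaching, overlapping nuclei in z, slow
drifts, or non-Gaussian noise. Passing therefore demonstrates that the
implementation computes its definitions correctly and recovers planted
structure under the stated model, not that the model captures every
property of real recordings.

Problem sizes used by the tests and the acceptance script: 500 cells /
full 40-min protocol for evoked recovery; 200 cells / 650 s for
spontaneous and 40-cell regions over 20 seeds for correlation recovery;
two-plane 192 × 160 px movies for segmentation; 10,000 null pairs for
the type-I calibration. These sizes give stable estimates (recovery
errors well inside their tolerances) while keeping a full run within a
couple of minutes.

# Known limitations

* Region assignment is mask lookup at the centroid; no atlas
  registration. Masks must be supplied (or generated).
* Motion correction is integer-pixel rigid translation per plane.
* No spike inference, no transient/event detection, no partial or
  lagged correlations, no multiple-testing correction (none is applied
  in the source analyses).
* The 1-Hz resampling slightly attenuates white components relative to
  the autocorrelated calcium term, so measured correlations sit a few
  hundredths below the full-rate analytic value; the recovery tolerance
  (±0.05) absorbs this, and the bias direction is stated here rather
  than corrected, to keep the measured quantity exactly what the
  analysis chain produces.
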