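---
title: "Event-based synchronization of heel kinematics and ground reaction forces"
author: "grfsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based synchronization of heel kinematics and ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfsync)
```

## The problem

Markerless motion capture estimates body kinematics from synchronized
smartphone video (typically 60 fps), while force platforms record ground
reaction forces on their own acquisition clock (typically 1000 Hz).
Without a shared hardware trigger the two recordings of the same
functional movement — a squat, a lunge, a step — start at arbitrary
relative times, and any analysis combining kinematics with kinetics is
meaningless until the clocks are reconciled.

`grfsync` aligns the two streams on a single observable physical event:
the instant the heel meets the ground. The heel contact is visible in
both modalities — as the minimum-then-rise of the vertical heel
coordinate, and as the onset of vertical loading in the vGRF — so the
difference between the two detected event times *is* the clock offset,
and subtracting it re-times the force stream onto the kinematic clock.

## The pipeline

For a trial with heel channel $h$ (60 Hz) and vertical force $F$
(1000 Hz):

1. **Heel preprocessing.** $h$ is min–max normalized to $[0, 1]$,
   despiked with a 5-sample centered median filter, and smoothed with a
   cascade of two 4th-order Butterworth low-pass filters (3 Hz cutoff),
   each applied bidirectionally.
2. **Force preprocessing.** $F$ is low-pass filtered with a 4th-order
   30 Hz Butterworth filter, also bidirectionally.
3. **Heel-contact detection.** With $m = \min h$ and $M$ the maximum of
   $h$ after the stabilization period,
   $$\mathrm{thr}_h = (M - m)\,c + m,$$
   with $c = 0.2$ for bilateral tasks and $c = 0.6$ for single-leg
   tasks. The contact is the first sample after a local minimum that is
   ascending and crosses $\mathrm{thr}_h$ from below.
4. **Force-onset detection.** With $b$ the mean of the first 10 samples
   and $\sigma$ the population SD of the whole trace,
   $$\mathrm{thr}_F = b + 0.1\,\sigma,$$
   the onset is the first post-baseline sample strictly above
   $\mathrm{thr}_F$.
5. **Offset and shift.** $\Delta t = t_{\text{onset}} -
   t_{\text{contact}}$ (negative when the force clock runs ahead); the
   force stream's clock is corrected by $-\Delta t$.
6. **Cycle normalization.** All channels are expressed on a 0–100%
   movement-cycle axis (101 points) from the contact instant to the end
   of the shorter stream.
7. **Agreement metrics.** Pairs of amplitude-normalized (0–1),
   time-normalized curves are compared with Pearson $r$, RMSE and MAE.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| heel threshold factor | 0.2 bilateral / 0.6 single-leg | — | fraction of the post-stabilization range above the global minimum |
| stabilization period | 30 samples (0.5 s at 60 Hz) | samples | excludes setup transients from the baseline maximum |
| force baseline window | 10 samples | samples | resting segment averaged into the baseline |
| force threshold factor | 0.1 | — | SD multiples above baseline |
| SD scope | whole trace | — | segment the SD is computed over (`"baseline"` available) |
| heel filter | 2 × (order 4, 3 Hz, zero-phase) | — | heel smoothing cascade |
| force filter | order 4, 30 Hz, zero-phase | — | force anti-noise filter |
| median window | 5 | samples | despiking window |
| cycle points | 101 | — | 0–100% at 1% steps |
| quiet gap | 0.25 | s | minimum quiet spell separating loading episodes (QC) |

The stabilization period and the bilateral tie-break (both heels
crossing in the same frame resolves to the left channel) are
conventions this package had to fix because no canonical value exists;
both are configuration-exposed and logged in every report.

## Numerical choices

* **Zero-phase filtering.** Every default filter stage is bidirectional
  because a causal low-pass delays every edge and would bias the
  detected event times — the one thing this pipeline exists to get
  right. Each pass pads the signal with an odd (point-mirrored)
  reflection of `3 × order` samples per end and initialises the filter
  state at its steady-state response to the first padded sample, which
  makes the DC gain exactly 1 (a constant signal passes through to
  machine precision) and keeps edge transients out of the analysed
  span. A signal must therefore be longer than `3 × order` samples.
  The directionality of the force filter is a package choice: the
  onset-latency argument applies to it with full force, so it is
  zero-phase as well, and the choice is recorded in the provenance log.
* **Median before low-pass.** The heel chain runs
  normalize → median → Butterworth. Despiking first removes an isolated
  tracking outlier outright; low-passing first would smear the spike
  across neighbouring samples where no median window can recover it
  (measured residual ≈ 4 × 10⁻² of range for a half-range spike, versus
  0 with the despike-first order).
* **No re-clamping.** Filter ringing can push the normalized heel trace
  slightly outside $[0, 1]$ (bounded by ±0.05 in practice). Values are
  not clamped: clamping flattens exactly the slopes the contact
  detector measures.
* **Strict crossings.** Detectors require strictly-greater-than, so a
  constant trace (SD = 0, threshold = baseline) fails loudly with a
  no-event error instead of firing at sample 0.
* **Plateaus.** A flat stretch at a minimum resolves to the plateau's
  last sample, so "ascending after the minimum" is well defined on
  quantized data.
* **Shifting is clock arithmetic.** The offset correction adjusts
  `start_time` only; the 1000 Hz samples are never rolled or
  interpolated, so no smoothing is introduced. Resampling to a common
  grid, when requested, is an explicit separate step after shifting,
  with linear interpolation and exactly preserved endpoints.
* **Monotone thresholds, scoped.** Raising the heel threshold factor
  can only delay detection on a single-valley trace with a monotone
  ascent — the geometry the detector is designed for. On signals with
  many minima a higher threshold can legally fire on an earlier ascent
  that a lower one skips, so the monotonicity property is asserted on
  contact-shaped traces.
* **Failures are data.** A no-event or degenerate-signal outcome
  returns a failed result object carrying its reason; batch processing
  counts these into a success rate instead of aborting, which makes
  "what fraction of a session could be aligned" a first-class
  statistic.

## The preliminary-step QC flag

A participant sometimes takes an extra step onto the platform before
the actual movement. The resulting transient force peak makes the onset
detector fire prematurely, which silently corrupts the offset. The QC
check segments the filtered vGRF into *loading episodes*: maximal runs
above the onset threshold, merged when the signal fails to stay back
below threshold for at least the quiet gap (0.25 s), and ignoring
excursions shorter than 0.05 s (noise). A trial whose final episode is
preceded by at least one earlier episode is flagged, and the start of
the final episode is reported as the candidate true onset so the run
can be repeated with a manual override. The flag is advisory: the
pipeline still reports the offset it computed.

## The synthetic-trial generator

Real validation recordings are not distributable, so the package ships
a generator whose trials carry exact ground truth, making every stage
testable end to end:

* **Heel**: an elevated plateau, a raised-cosine descent (0.5 s)
  reaching its minimum at the contact instant, and a raised-cosine
  rebound (0.08 s) to 70% of the drop height (85% for single-leg
  trials, so the 0.6 threshold is crossable). Gaussian noise is added
  before filtering, mirroring the real processing order.
* **vGRF**: zero (or a configurable resting load) until the contact
  instant *as read on the force clock*, a raised-cosine rise to body
  weight over 0.2 s, then a slow 0.4 Hz loading oscillation emulating
  the squat cycle. The injected clock offset is exact by construction.
* **Extra step**: an optional raised-cosine force bump (0.3 s wide,
  half body weight) ending well before the main loading, reproducing
  the documented failure mode.

The contact-dynamics constants (rebound 0.08 s to 70%, loading rise
0.2 s) were fixed at generator-design time so that the heel detector's
latency from the true minimum and the force detector's latency from the
true onset agree to within a few milliseconds; with matched latencies
the recovered offset estimates the injected one without systematic
bias, which is what makes exact offset-recovery testing meaningful. On
the default bank (offsets uniform in ±2 s, contact time uniform in
2.6–3.4 s, 2% range noise, 200 trials) the pipeline recovers the
injected offset within one kinematic sample (1/60 s) in ≈ 99% of
trials, and in 100% of noiseless trials.

What the generator deliberately does **not** emulate: the structured,
auto-correlated error of video pose estimation (dropouts, identity
swaps, depth ambiguity), double-peak impact-transient GRF shapes, or
soft-tissue artefact. Passing the synthetic suite therefore
demonstrates the correctness of the algorithm under its stated
assumptions — a detectable single contact in both channels — not its
robustness to every pathology of real recordings; the failure-handling
and QC paths are how those pathologies surface in practice.

## Problem sizes used by the test suite

The shipped tests run the 200-trial recovery bank (noisy and
noiseless), 1000-signal detector–oracle comparisons, 1000-pair metric
comparisons, a 100-trial QC bank with 20% corruption, and 1-minute
equivalent filter probes; the full suite completes in well under a
minute on a single core, and the same computations are reproduced from
scratch by `scripts/acceptance.R`.

## Known limitations

* Offset resolution is bounded by the kinematic sample period
  (16.7 ms at 60 Hz); no sub-sample interpolation of the heel event is
  attempted.
* The method assumes one analysable contact per trial; cyclic gait with
  many contacts needs per-cycle segmentation upstream.
* Amplitude agreement between measurement systems is outside the
  method's control: it aligns time, not magnitude.
* The success-rate statistic of a batch depends on the composition of
  that batch; it is a property of the data set, not a universal
  constant.
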