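---
title: "Estimating the apnea-hypopnea index from single-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the apnea-hypopnea index from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Obstructive sleep apnea is diagnosed and graded by the apnea-hypopnea index
(AHI): the number of apnea and hypopnea events per hour of sleep, normally
scored from attended polysomnography. Both event classes are defined as
airflow reductions lasting at least 10 s. Because polysomnography is
expensive and uncomfortable, a long line of work tries to score
sleep-breathing events from signals a wearable can record — here, a single
ECG lead. The physiological basis is the cyclic cardiac response to an
apneic event: relative bradycardia while airflow is reduced (rising R-R
intervals, RRI), followed by an abrupt sympathetic rebound with
tachycardia and hyperventilation when breathing resumes, which also
modulates the R-peak amplitude (RPA) through respiratory effort.

`sleepahi` implements the full pipeline: signal conditioning, R-peak
detection, windowed RRI/RPA inputs, a per-segment neural sequence scorer,
and recording-level AHI estimation. A synthetic annotated ECG generator
stands in for clinical data, so every stage is testable end to end.

## From waveform to model inputs

1. **Conditioning.** Recordings (nominally 200 Hz) are downsampled to
   100 Hz and bandpass filtered to 3-45 Hz. The filter is a 4th-order
   Butterworth applied forward and backward (`signal::filtfilt`), chosen
   because zero-phase filtering leaves R-peak *times* untouched; only the
   band edges are externally prescribed.
2. **R peaks.** An adaptive-threshold detector in the style of Christov's
   steep-slope method scans a rectified, 40-ms-smoothed derivative
   envelope; the threshold re-seeds at 60% of each accepted beat's envelope
   peak (averaged over the last five beats) and decays after a 220 ms
   refractory period. The detector is pluggable — `preprocess_recording()`
   accepts any function with the same contract, which the tests specify
   behaviorally (exact beat counts and <20 ms timing error on clean
   synthetic input).
3. **Derived series.** RRI takes the value `t[i+1] - t[i]` stamped at the
   *later* peak (a convention choice; the timestamping side is not
   externally constrained); RPA passes peak amplitudes through. Intervals
   outside 0.3-2.0 s — almost always missed or spurious detections — are
   replaced by the median of plausible intervals within ±30 s before any
   interpolation.
4. **Windows.** The recording is cut into a fixed 10-s grid anchored at the
   start (trailing partial segment dropped). Each segment t is extended by
   the 25 s before and after into a 1-min window, and by its two preceding
   and two succeeding 1-min windows into a 5-min window, i.e.
   `[10t-25, 10t+35)` and `[10t-145, 10t+155)` — an overlapped dataset with
   10-s step. Both windows are linearly interpolated onto fixed grids of
   180 and 900 points per channel (linear interpolation is
   shape-preserving; nothing beyond "interpolated" is prescribed). Windows
   that reach past the recording edges replicate the nearest available
   value so every segment gets a prediction; a recording in which fewer
   than two beats are detectable falls back to median-filled channels and
   is flagged.

## Labels, events and the three AHIs

A segment is labeled positive only when it lies **entirely inside** one
annotated event (strict enclosure); apnea and hypopnea both count, and
sub-10-s annotations can never produce a positive label. Because an event
longer than 20 s covers several consecutive segments, maximal runs of
positive segments are collapsed into single events before counting.

Three AHIs are compared per recording:

* **true AHI** — annotated events divided by recording duration in hours
  (for synthetic data the recording stands in for total sleep time);
* **target AHI** — collapsed event count of the *label* track divided by
  the time spanned by the segment grid: the ceiling a perfect classifier
  could reach;
* **predicted AHI** — the same computation on thresholded model scores
  (threshold 0.5 by default).

The strict rule trades sensitivity for label purity: short events that
straddle a grid boundary enclose no segment, and two events whose labeled
runs touch merge into one count. Both effects are asserted in the tests;
across simulated corpora the true and target AHI still correlate at
r > 0.99 because the losses are nearly proportional across recordings.

## The scorer

Each 10-s step feeds a dual-path convolutional feature extractor:

* **deep path** on the 2x180 1-min input: four blocks of 1-D convolution
  (kernel 5; widths 16, 32, 64, 64), each batch-norm + ReLU + max-pool 2;
* **shallow path** on the 2x900 5-min input: two blocks (kernel 11; widths
  16, 32; max-pool 4);
* both paths are global-average-pooled per channel, concatenated (96
  channels), reweighted by squeeze-and-excitation channel attention
  (reduction 8), and projected by a fully connected layer to a 128-d
  feature vector per step.

A single-layer unidirectional GRU (hidden 128, dropout 0.1 on its output)
consumes the per-recording feature sequence; a final fully connected layer
and logistic sigmoid yield one score per step. Only the module roles, the
two input resolutions and the 128-d feature width are externally fixed;
the specific widths, kernel sizes, GRU directionality and size are this
package's defaults, chosen to honor the deep-narrow/shallow-wide asymmetry
at a size a CPU can train. A bidirectional flag exists for comparison;
unidirectional is the default and gives the causality guarantees the tests
assert (truncating a sequence never changes earlier scores).

The loss is masked binary cross-entropy over batches of whole recordings
padded to the batch maximum, with a positive-class weight equal to the
training-set negative/positive ratio — segments with events are a small
minority, and an unweighted loss stalls at the trivial all-negative
solution. Inputs are z-scored per channel with training-set statistics.
All forward and backward passes are written in this package (im2col +
BLAS for convolutions, fused compiled kernels for
normalisation/rectification/pooling, a hand-written GRU and Adam); their
correctness is guarded by finite-difference gradient checks in the test
suite, in both training and evaluation mode.

## Training protocol

`train_control()` defaults follow the reference protocol: Adam with betas
(0.9, 0.999), initial learning rate 1e-4, batches of 16 recordings, up to
1000 epochs with a 10-epoch warmup, plateau scheduling (factor 0.1,
patience 10) and early stopping. The monitored quantity and the early-stop
patience (validation loss, patience 30) are this package's choices.
Cross-validation utilities (`split_train_test()`, `make_folds()`) group by
patient, never letting one patient's recordings straddle a split; the
property is asserted programmatically on every fold construction.

The end-to-end checks in the test suite use a deliberately small protocol:
80 recordings of 2 h (60/20 patient-disjoint train/test), 3 epochs,
batches of 4 recordings, learning rate 1e-3, no validation split (with a
10-epoch warmup convention, scheduling and early stopping are inert in so
short a run). On this corpus the task is designed to be learnable quickly,
and a convergence probe on a separate 16-recording corpus showed pooled
AUROC above 0.8 within a handful of optimiser steps; three epochs leave
a comfortable margin above the asserted thresholds while keeping the whole
suite CPU-friendly.

## The synthetic generator

`sim_config()` describes the study corpus. Defaults: 80 recordings of 2 h
at 200 Hz, mean heart rate 70 bpm, per-recording event rates drawn
uniformly from 5-60/h (the clinically relevant AHI range), event durations
uniform in 12-40 s (mostly the 10-20 s regime typical of scored events),
35% hypopneas, minimum inter-event gap 10 s.

The generator synthesises only what the downstream pipeline consumes:

* an event schedule (sequential placement with exponential slack so the
  expected onset-to-onset spacing matches the drawn rate);
* an RR tachogram: baseline RR = 60/HR with 20 ms per-beat Gaussian
  jitter; during an event the RR rises by the class's modulation depth
  (apnea 0.25, hypopnea 0.125 — half depth, making hypopnea the harder
  class by construction) under a cosine-ramped trapezoidal envelope, then
  dips to half depth below baseline for ~10 s (the rebound tachycardia);
* beat amplitudes with a 5% respiration-frequency oscillation, suppressed
  during events and transiently tripled afterwards (post-event
  hyperventilation);
* a waveform of amplitude-scaled biphasic QRS-like templates (~0.1 s wide,
  R-peak within one sample of the beat time) plus 0.2 mV sinusoidal
  baseline wander at 0.2 Hz and 0.05 mV white noise.

What it deliberately does **not** emulate: P/T waves or QRS morphology
changes, ectopic beats and arrhythmia, movement artifacts, electrode
dropouts, sleep-stage structure, or any particular clinical AHI
distribution. Passing the end-to-end checks therefore demonstrates that
the pipeline's mechanics — labeling, windowing, learning, AHI collapse —
are sound and that event-locked RRI/RPA signatures of this strength are
recoverable; it says nothing about performance on real polysomnography,
where noise, arrhythmia and weaker autonomic responses dominate the
difficulty.

## Numerical choices and degenerate inputs

* Interpolation grids are half-open (`n` points from `start` to
  `end - step`), matching the half-open segment convention.
* Batch-norm uses eps 1e-5 and momentum 0.1; evaluation uses running
  statistics, and the backward pass distinguishes the two modes.
* The AUROC is the tie-aware normalized Mann-Whitney statistic — exact,
  not a binned approximation; undefined metrics (empty class, zero
  variance) are reported as `NA`, never silently as 0.
* F1 defaults to the standard precision-recall harmonic mean
  `2TP/(2TP+FP+FN)`; a literal sensitivity/specificity harmonic-mean
  variant is available behind `f1 = "sens_spec"` for comparison with
  texts that describe F1 that way.
* Degenerate inputs error loudly: empty tracks, single-class AUROC,
  overlapping annotations, beat spacing narrower than the QRS template,
  infeasible event densities.

## Limitations

The scorer is trained and validated on synthetic data only; absolute
metric values reported by this package's checks characterise the pipeline,
not clinical performance. The strict-enclosure/collapse construction
slightly undercounts events by design (documented and asserted), and the
10-s grid bounds how finely event boundaries can be localised. Training
beyond desk scale (hundreds of 8-h recordings, full 1000-epoch schedules)
is out of scope for the bundled protocol, though nothing in the code
limits it.
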