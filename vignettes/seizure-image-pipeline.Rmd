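---
title: "Classifying seizures from EEG plot images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying seizures from EEG plot images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegplotnet)
```

## The problem

Psychogenic non-epileptic seizures (PNES) account for a quarter to a third
of epilepsy-monitoring-unit discharge diagnoses, and distinguishing them
from epileptic seizures (ES) drives treatment: anti-seizure medication and
surgery on one side, psychotherapy on the other. The discrimination is made
by epileptologists reviewing EEG *waveform plots* — not raw signals — on
clinical review software. `eegplotnet` implements an image-based pipeline
that emulates that visual review: multichannel EEG is band-pass filtered,
re-derived into clinical display montages, rendered as calibrated waveform
plot images, screened by two segment-level filters, classified by a
convolutional network, and scored with standard diagnostic metrics.

Because clinical EEG from monitoring units cannot be redistributed, the
package ships a seeded synthetic EEG generator as a first-class module. The
generator defines the study conditions under which every downstream stage
is exercised and tested.

## Signal model of the synthetic generator

Each synthetic event is a 21-channel referential recording (10–20 system
plus FT9/FT10) at 250 Hz (1000 Hz configurable), 60 s long by default,
composed from three regimes:

* **Interictal background** — every channel mixes a band-limited alpha
  oscillation (carrier drawn per channel in 8–12 Hz, slowly
  amplitude-modulated at ~0.3 Hz, amplitude 10 µV) with 1/f-shaped noise
  (5 µV RMS; the 1/f shaping is flattened below 1 Hz to keep variance
  finite). These defaults put background deflections at roughly 20–30 µV
  peak-to-peak, a typical awake adult scalp EEG scale.
* **Ictal discharge** (ES events only) — a rhythmic discharge whose
  instantaneous frequency sweeps linearly from 5 Hz to 2.5 Hz while its
  amplitude ramps from a quarter to the full 100 µV, added to channels
  with temporal-chain-dominant weights. The slowing, amplitude build-up
  and temporal emphasis imitate the evolution of a typical focal-onset
  seizure; half-second cosine tapers avoid step discontinuities. Each ES
  event carries one discharge of 25–35 s starting at a randomized time.
* **Movement/EMG artifact** (half of PNES events, by default) — bursts of
  band-limited noise (generated at 35–110 Hz with a +6 dB/octave tilt,
  matching the rising spectrum of surface EMG) mixed with 60 Hz mains
  pickup — electrode movement transiently breaks impedance and couples
  line noise — and a sub-hertz movement sway. After the clinical 0.3–70 Hz
  display filter the visible burst energy occupies 20–70 Hz. Default burst
  RMS is 300 µV with per-event amplitudes drawn at 0.3–1 × that value, so
  rendered bursts straddle the EMG pixel-density threshold: some PNES
  segments are removed by the filter, most survive.

Every random draw descends from a single integer seed via per-event
substreams (a stable hash of the event identifier), so a cohort is a pure
function of its configuration and seed regardless of generation order.

What the generator does **not** model: cortical source geometry and volume
conduction, inter-channel correlation structure of real EEG, eye-movement
and ECG artifacts, sleep architecture, electrode pop, or the heterogeneity
of real PNES semiology. Consequently, green end-to-end tests demonstrate
that the pipeline's machinery is correct and that the classifier can learn
visually separable classes at the stated recipe — they do not certify the
published clinical accuracies, which depend on real data.

## Filtering and montages

The display filter is the clinical 0.3 Hz low-cut / 70 Hz high-cut pair,
implemented as a 4th-order Butterworth band-pass applied forward-backward
(zero phase), the ubiquitous choice when waveform morphology must be
preserved for visual display. Channels are demeaned before filtering;
this removes DC exactly and keeps `filtfilt` edge transients negligible
(without it, a constant 50 µV offset leaves a ~1 µV residual mean from
the transient alone). A high cut at or above the Nyquist frequency is
rejected.

Four display montages are built in: the 18-derivation longitudinal
anterior–posterior bipolar "double banana" (`ap_bipolar`), the 19-channel
common-average reference (FT9/FT10 excluded from the average, a
configurable convention), the standard 18-derivation transverse bipolar,
and a longitudinal/transverse montage centred on FT9/FT10 (`phase1`).
The `phase1` derivation list is a fixed convention of this package
(inferior temporal chains Fp1–F7–FT9–T3–T5–O1 and Fp2–F8–FT10–T4–T6–O2
plus FT9–Cz–FT10): no published list exists, and the choice only affects
training-set diversity — evaluation always uses `ap_bipolar`.

## Rendering: from microvolts to pixels

The renderer owns the calibration contract of the pipeline:

* `width_px` = 1000 horizontal pixels spanning `epoch_s` = 10 s, so the
  displayable bandwidth is `width_px / epoch_s` = 100 Hz;
* `px_per_uv` = 1 vertical pixel per microvolt;
* one lane per derivation, stacked in montage order at
  `lane_spacing_px` = 25;
* black 1-px traces on white, no gridlines or channel labels (labels would
  let a classifier shortcut on text).

Samples are mapped to pixel columns by index; each column draws the
min–max envelope of its samples, extended to the previous column's closing
position for continuity. The envelope preserves spikes that plain
decimation would erase — at 250 Hz and 1000 px / 10 s there are only 2.5
samples per column, so this matters. Deflections are clipped to the lane
band (half a lane spacing either side of the baseline); clinical viewers
instead let traces overlap neighbouring lanes, but clipping is
deterministic and keeps lanes geometrically independent. EEG polarity
convention (negative up) is the default and configurable. Rendering is
fully deterministic: identical inputs give byte-identical PNGs.

## Segment processing

Each 10 s epoch image is split into two equal-width 5 s segments (odd
trailing column discarded), then filtered in a fixed order:

1. **Ictal-content rule** — an ES segment is kept only if its time window
   overlaps the annotated ictal intervals by at least `min_ictal_s` = 2 s;
   PNES segments always pass this rule. This computable overlap rule
   stands in for the visual review used when clinical datasets are
   prepared by hand.
2. **EMG pixel-density rule** — the segment's 8-bit values are summed over
   all pixels and RGB channels; a sum strictly below the threshold drops
   the segment as EMG-blackened. The canonical constant is 18 million at
   a reference area of 540,000 px (a 1000-px-wide screen with 21 lanes at
   the default spacing); for any other image area the threshold scales
   proportionally, and at the reference area the constant applies
   verbatim.
3. **Pad** to square with RGB (255, 0, 0). Pure red is the fixed
   convention of the upstream preparation recipe this package reproduces
   (possibly a typo for a neutral grey in the original description — the
   colour is configurable, and since the pad colour is constant across
   classes it carries no label information either way).
4. **Resize** bilinearly to 224 × 224 and **normalise** by 255. Padding
   precedes normalisation because the pad colour is specified in 8-bit
   units; since bilinear interpolation is linear, resizing before or
   after the division by 255 is mathematically identical.

Split assignment to train/validation/test is randomized **at the event
level** — all segments of one seizure share a split — with a single
seeded, proportional draw (largest-remainder rounding). An event-level
leakage check runs before training and aborts on violation; within-event
segments are far too correlated to straddle splits.

## Classifier

The reference backbone of the recipe is pretrained MobileNetV2 fine-tuned
end-to-end. Pretrained weights require a download; in this package
requesting `mobilenet_v2_pretrained` offline raises an explicit error,
and all shipped training uses `tiny_cnn`, a deliberately small CPU-scale
network trained from random initialisation with the *same recipe*: plain
minibatch SGD (no momentum, decay or schedule) at learning rate 0.05,
batch size 32, categorical cross-entropy, and after every epoch the
validation loss is evaluated — the returned weights are those of the
epoch with the lowest validation loss. The epoch budget is configurable
(`max_epochs`, default 30; the pipeline default is 20) because the
checkpoint rule makes the exact count non-critical.

`tiny_cnn` reduces the RGB input to an ink-density map (one minus mean
brightness, so trace ink is the signal and white background is zero),
bilinearly pools it to 64 × 64 — chosen so individual channel lanes
remain a few pixels tall; at 32 × 32 the lanes collapse below two pixels
and held-out accuracy degrades — then applies one 5 × 5 convolution with
8 filters, ReLU, 2 × 2 mean pooling, and a dense two-node softmax head
(~7,000 parameters). Ties at exactly (0.5, 0.5) classify as PNES, the
conservative default (no seizure is called without evidence).

## Evaluation

With ES as the positive class, the evaluation module computes the 2 × 2
confusion matrix; sensitivity, specificity, PPV, NPV and accuracy; a 95%
Wilson score interval for each metric from its own numerator and
denominator (exact normal quantile, z = 1.959964); element-wise pooling
of per-site matrices for combined metrics; and a threshold-swept ROC
curve whose trapezoidal AUC equals the tie-corrected Mann–Whitney
probability estimator. Metrics with zero denominators are reported as
undefined (`NA`), never as zero. All metrics are image-level, matching
how the published confusion matrices count; an event-level aggregation
is deliberately not the default.

Two of the thirty published Wilson bounds this package reproduces are
internally inconsistent with the Wilson formula (upper bounds 88.0 and
88.9 where Wilson gives 87.8 and 88.7, with the other 28 matching at
printed rounding); the tests lock the computed values against an
independent score-test-inversion oracle and note the discrepancy as a
source-table typo.

## Numerical choices and degenerate inputs

* Filter: single Butterworth band-pass design (a separate high-pass +
  low-pass cascade attenuates a 10 Hz sine by ~29% and was rejected);
  per-channel demeaning before `filtfilt`.
* Renderer: sample-index column binning (every sample contributes to
  exactly one column); integer row rounding; odd-width split drops the
  final column; zero-derivation montages and out-of-bounds windows are
  errors; recordings shorter than one epoch yield an empty window list
  with a warning.
* Resize: EBImage's bilinear resize point-samples the source; a
  2 × 2-block checkerboard downscaled by exactly two therefore returns
  pure block values rather than interior averages. Tests use
  linear-ramp preservation (exact for bilinear interpolation) as the
  resize oracle instead.
* EMG filter: strict `<` at the threshold, monotone under brightening by
  construction (the statistic is a sum).
* Wilson interval at k = 0 (or k = n) has an exact 0 (or 1) boundary.
* AUC with a single class present is an error; all-tied scores give 0.5.

## Problem sizes

Shipped end-to-end runs use a 20-event cohort (10 ES / 10 PNES, 60 s
each), `ap_bipolar` for evaluation plus all four montages for training
diversity, yielding roughly 200 kept 5-s segments — small enough for
interactive use on one CPU core (a full pipeline run takes a few
minutes) while leaving every stage, filter and both outcome classes
well populated. The tiny backbone separates this cohort essentially
perfectly by score ranking (held-out AUC ≥ 0.99 across seeds) and
typically reaches ≥0.9 held-out image accuracy within 20 epochs; with
only ~30 test images the hard-label accuracy varies by a few points from
seed to seed. This is a learning-sanity property of separable synthetic
classes, not a reproduction of the published clinical accuracies
(86.9% / 87.3%), which would require the original recordings.

## Known limitations

* The synthetic cohort is visually far easier than clinical EEG; PNES
  background here is clean alpha, whereas real PNES EEG shows the full
  range of normal variants and movement patterns.
* The renderer is this package's own (the clinical viewers are
  proprietary); only the published calibration constraints — width/epoch
  relation and 1 px/µV — are reproduced, not pixel-exact screenshots.
* The EMG threshold's reference area is a documented convention; the
  original screenshot geometry is unpublished.
* No EDF I/O: recordings enter as in-memory objects; cohort manifests,
  images, configurations and metrics are exchanged as CSV/PNG/JSON.
* `mobilenet_v2_pretrained` is a declared backbone that errors without
  weights; no attempt is made to reproduce the published site-level
  scores or AUCs (0.92/0.94), which depend on unavailable data.
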