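---
title: "Direction- and severity-aware fall detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction- and severity-aware fall detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Waist-worn inertial measurement units (IMUs) sample tri-axial
acceleration and angular rate continuously; fall-detection systems must
decide from those streams not only *whether* a fall occurred but, for
clinically useful triage, *which way* the person fell (forward,
backward, lateral) and *how severely* (a hard, unbroken impact versus a
soft one dampened by support). `fallwatch` implements a complete
pipeline for this ten-class problem — four activities of daily living
(walking W, jogging J, sitting S, standing SB) plus six fall classes
(FHF, BHF, LHF, FSF, BSF, LSF: direction crossed with hard/soft) — over
recordings in the SisFall plain-text format (nine integer columns at
200 Hz, filename `<code>_<subject>_R<NN>.txt`). A seven-class variant
pools the four ADLs into a single class.

## Pipeline

1. **Parsing and unit conversion.** Raw sensor integers become physical
   units by the linear map `value = (2*range/2^bits)*raw`; the default
   is the wide-range ±16 g/13-bit accelerometer and ±2000 deg/s/16-bit
   gyroscope. Which accelerometer to read is configurable
   (`sensor_config()`): downstream peak finding is invariant to
   positive per-channel scaling, so this choice cannot move a window.
2. **Windowing.** The support magnitude vector
   `SMV = sqrt(ax^2 + ay^2 + az^2)` is computed per sample; the window
   of 3 s (L = 600 samples) is centred on its maximum, ties broken at
   the earliest index. The long 100 s continuous walking/jogging
   recordings (codes D01–D04) are instead cut into non-overlapping
   consecutive windows, remainder discarded.
3. **Augmentation.** Minority classes (SB and all six fall classes) are
   expanded 4× in the *training split only*: additive Gaussian noise
   (sd 0.01 in converted units), one uniform amplitude factor in
   [0.8, 1.2] per window, and upsample/decimate resampling with factor
   10.
4. **Feature extraction.** A 1-D CNN — four conv layers of 64 filters,
   kernel length 3, each followed by batch normalisation and ReLU, with
   average pooling (length 2) after the first three — is trained with a
   temporary fully connected softmax head by plain SGD (learning rate
   0.01, batch 20), selecting the epoch with the best validation UAR
   (early stopping, patience 20). At L = 600 the flattened final
   feature map has 71 × 64 = 4544 columns.
5. **Classification.** The softmax head is removed and an XGBoost
   multi-class model is fitted on the flattened features, its tree
   count, depth and learning rate chosen by exhaustive grid search on
   validation UAR (ties: fewer trees, then shallower).
6. **Evaluation.** Confusion-matrix metrics per class; the headline
   metric is the unweighted average recall (UAR), the plain mean of
   per-class recalls, deliberately insensitive to class imbalance.
   Fall recalls roll up by direction (two-class means) and severity
   (three-class means); the falls-only average is the six-class mean.

## Design choices in the open points

Several details of this architecture admit more than one reading; the
package fixes them as follows and exposes each as configuration.

* **Window parity.** With an even L the peak cannot be exactly central;
  the window spans `[p − L/2, p + L/2)`, i.e. 300 samples before the
  peak and 300 from it on. Deterministic and symmetric to within one
  sample.
* **Boundary clamping.** A peak within 1.5 s of either end shifts the
  window minimally to fit rather than zero-padding: fabricated samples
  inside a learned feature extractor's input are worse than a slightly
  off-centre peak. Recordings shorter than L raise an error naming the
  recording — real recordings (≥ 12 s) never trigger it.
* **Layer order and geometry.** Conv → batch-norm → ReLU, pooling
  length/stride 2, no padding, conv stride 1. The net consumes raw
  converted units; no input standardisation beyond the batch-norm
  layers (a per-channel standardisation flag exists but defaults off).
* **Resampling kind.** Linear interpolation, then decimation by
  stride; exact on affine signals. Cubic interpolation would also be
  defensible; linear is the minimal reading and is what
  `aug_resample()` implements.
* **One scale factor per window**, not per channel: a loosened strap
  or a lighter subject scales all axes together, and a single factor
  preserves inter-axis geometry (it commutes with the SMV).
* **Mean-of-recalls UAR.** The per-class recall mean uses exactly one
  term per class. This is verified in the tests against reference
  per-class tables whose printed averages and direction/severity
  roll-ups it reproduces to the printed precision.
* **Zero denominators** in precision/recall/specificity report 0 with
  a warning rather than NaN, keeping macro averages defined on
  degenerate splits.
* **No reweighting at the XGBoost stage**: class imbalance is already
  addressed by augmentation.
* **Seeding.** One global seed deterministically derives the split,
  augmentation, CNN and XGBoost seeds, so a pipeline run is
  reproducible end to end (up to BLAS floating-point ordering).

The CNN itself is implemented in-package as vectorised matrix
operations (im2col convolution with BLAS matrix products and
hand-written backpropagation). This keeps the dependency surface to
base R linear algebra and makes the arithmetic of every layer
inspectable; the trade-off is that very large architectures would be
slow, which this four-layer network is not.

## The synthetic data generator

`simulate_dataset()` emulates the *file layout and signal character* of
waist-worn IMU recordings so the entire pipeline can run without the
real dataset: gravity as a 1 g baseline, periodic gait oscillation for
W/J (jogging faster and larger), a smooth postural transition with a
transient for S, quasi-static sway for SB, and for falls a single
Gaussian impact transient whose axis and sign encode direction
(forward +x, backward −x, lateral +y), whose amplitude encodes severity
(hard 6 g, soft 3 g), soft falls adding a smaller pre-impact support
bump, both adding a post-impact orientation change. Everything is
quantised to sensor integers through the inverse of the unit
conversion (round-trip within one least significant bit, verified in
the tests).

The model is additive and piecewise-deterministic, **not**
biomechanically realistic: no inter-subject kinematic variation beyond
amplitude/frequency jitter, no sensor drift, no hesitation or
near-falls, and class-conditional signatures far cleaner than real
accelerometry. Impacts are placed at least 1.6 s from the recording
ends, so peak windows never clamp on synthetic data; the clamping
branch is exercised by purpose-built fixtures instead. Consequently a
high test UAR on synthetic data demonstrates that the pipeline's
mechanics (labelling, windowing, augmentation, feature learning, head
swap, aggregation) are correct — it says nothing about accuracy on real
falls, where published UARs for this task sit in the high 80s.

Default generator conditions: 2 subjects, the standard per-code trial
counts (one long recording for each of D01–D04, five 12 s trials for
every other code), 200 Hz. That yields 524 windows with realistic
imbalance (10 windows for the rarest fall classes, ~150 for walking).

## Problem sizes used in the shipped runs

The test suite and the acceptance script train on the 2-subject
synthetic dataset with `max_epochs = 30` and an XGBoost grid of
{50, 150} trees × {3, 6} depth × learning rate 0.3 — a deliberately
small demonstration grid; the package default `xgb_search_space()` is
the full {100, 300, 500} × {3, 6, 9} × {0.05, 0.1, 0.3}. On these
sizes the whole simulate → preprocess → train → evaluate chain takes a
few minutes and reaches a perfect or near-perfect test UAR, well above
the 90% gate the tests assert.

## Known limitations

* Synthetic separability means the end-to-end gate validates pipeline
  correctness, not real-world performance; reproducing published
  real-data numbers requires downloading SisFall and substituting its
  directory for the simulated one (`read_sisfall_dir()` accepts either).
* Only the three stated augmentations are implemented — no rotation,
  permutation, time-warping or mixup.
* No pre-/post-impact phase segmentation and no overlapping windows.
* Plain SGD without momentum or schedules; adding either is a
  one-line change in `cnn_sgd_step()` but is deliberately not default.
* The elderly-subject subset of SisFall (SE codes) is read like any
  other subject; no age-specific bookkeeping.
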