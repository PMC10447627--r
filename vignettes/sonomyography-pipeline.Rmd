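---
title: "From A-mode ultrasound echoes to prosthesis kinematics: the sonokin pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From A-mode ultrasound echoes to prosthesis kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonokin)
library(dplyr)
```

## The problem

Powered knee/ankle prostheses need a sensing channel that reflects what the
user's residual-limb muscles are doing. A-mode ultrasound is a cheap,
wearable alternative to surface EMG and to 2-D (B-mode) imaging: each
transducer returns a 1-D echo-amplitude profile along tissue depth, and the
depths of high-echogenicity boundaries (muscle fascia) shift as the muscles
deform during walking. `sonokin` implements the offline analysis that maps
these echo profiles to four concurrent joint variables — knee position,
knee velocity, ankle position, ankle velocity — with one small regression
network per variable, and scores the predictions the way gait studies do
(normalized RMSE, filtering delay, gait-cycle peak timing, range recovery).

Because the human-subject recordings behind this kind of experiment are not
publicly deposited, the package ships a first-class synthetic-data module
that reproduces the statistical structure the analysis relies on, and the
whole pipeline is exercised end to end on that synthetic data.

## Acquisition model

The wearable system polls its 4 transducer channels sequentially at an
80 Hz tick: every 12.5 ms exactly one channel produces a fresh 997-sample
frame, so a full refresh of all four channels takes 50 ms, and each of the
two muscle groups (two anterior channels on the quadriceps side, two
posterior on the hamstrings side) is effectively sampled at 40 Hz. The 997
samples span 3.94 cm of tissue, i.e. ~0.004 cm per sample. These constants
are fixed in the package (`acquisition_timing()` derives the timing facts
from any simulated trial rather than hard-coding them in tests).

## Feature reduction

Each raw frame is reduced to 48 features (`extract_channel_features()`):

1. **Offset removal + rectification** (`preprocess_frame()`): `|x − mean(x)|`.
   The offset step is under-determined by the acquisition chain (the raw
   output may be signed RF or already non-negative); subtracting the frame
   mean is the simplest DC removal and makes the pipeline insensitive to
   either convention. Configurable (`mean` | fixed value | `none`).
2. **Envelope** (`envelope()`): centered 77-point moving average over depth.
   At the frame edges the window is truncated and the mean taken over the
   available samples; zero padding would manufacture artificial dips at the
   shallow and deep ends of echo envelopes (configurable `truncate` |
   `zero`). The window is centered, not causal: this is a per-frame
   operation over *depth*, not time, so causality is irrelevant.
3. **Trim + window means** (`trim_and_window()`): the deepest 37 samples are
   dropped (960 remain), the rest partitioned into 48 contiguous 20-sample
   windows in depth order, and each window's mean is one feature — roughly
   0.08 cm of tissue per feature.

The geometry is validated as a whole (`feature_geometry()` enforces
`trim + 48 × 20 = 997`), and the stages preserve non-negativity and are
scale-equivariant about the frame mean.

## Stream assembly and the train/test split

The model input at a tick is the 192-element concatenation of the most
recent 48 features of each channel, channel 1 in positions 1–48 through
channel 4 in 145–192 (`update_feature_vector()`, folded over a trial by
`build_supervised_dataset()`). Because only one channel refreshes per tick,
consecutive rows differ in exactly one 48-block. Emission starts at the
first tick at which all four channels have been observed (tick 3, 0-based):
the first three ticks are discarded rather than zero-filled, so no row ever
contains fabricated features. That costs 37.5 ms of data per trial — for
the default 8 s trial, 637 of 640 ticks are emitted. Labels are the
kinematic values at the emission tick itself (the task is concurrent
prediction, not forecasting), and feature rows never mix information across
trials.

A recording session is four walking trials: two comfortable-speed trials
for training, one held-out comfortable-speed trial (the *normal* testing
set) and one faster-paced trial (the *fast* testing set). `split_trials()`
partitions by trial role, never by position.

## The regressors

One network per joint variable (`train_regressor()`): 192 inputs, three
10-node fully connected layers each followed by ReLU, and a single linear
output — 2161 trainable parameters, small enough to run online later.
Choices the architecture alone does not pin down are made explicit and kept
deterministic:

- **Input/label scaling**: per-feature standardization and label
  centering/scaling from the training rows only; reported losses are
  rescaled to original units.
- **Optimizer**: full-batch L-BFGS on the mean squared error with analytic
  backpropagation gradients, iteration cap 1000, relative tolerance 1e-6.
  A quasi-Newton full-batch fit on 2161 parameters converges in seconds and,
  unlike stochastic optimizers, is bit-reproducible given the seeded
  He-style initialization.
- **No regularization, no early stopping**: the datasets (≈1300 rows) are
  smooth functions of gait phase and the network is tiny; the permutation
  control in the tests guards against the no-signal failure mode instead.

Hitting the iteration cap is reported as a warning with the loss trace kept
on the model object, and the model is still returned.

## Evaluation

`evaluate_experiment()` scores the four models on both testing sets:

- **Accuracy**: RMSE and normalized RMSE on the *unfiltered* predictions
  (no filter delay contaminates the accuracy number). The nRMSE denominator
  is the range (max − min) of the recorded signal over the evaluated
  segment; range normalization is the one simple convention that keeps
  position and velocity errors on a comparable percent scale, with `sd` and
  `mean` available as config options.
- **Smoothing**: predictions destined for delay/shape analysis pass through
  a 2nd-order low-pass Butterworth (cutoff 7 Hz, within the optimal band
  for walking signals) applied forward-only, as an online controller would
  (`causal_butterworth()`). The design comes from `signal::butter()`
  (bilinear transform); the filter state is initialized to the steady-state
  response of the first sample, so constants pass through exactly and there
  is no startup transient. Filtering *raises* nRMSE — the cost of the phase
  lag — which the tests assert as a directional property.
- **Delay**: lag maximizing the normalized cross-correlation (both signals
  mean-removed) within ±0.25 s, in ms at 12.5 ms per sample
  (`estimate_delay()`). A peak correlation below 0.5 flags the estimate
  unreliable; the fast testing set is excluded from delay reporting for
  exactly that reason.
- **Gait-cycle shape**: each stride (heel strike to heel strike) is
  linearly resampled to a 101-point 0–100% grid and averaged pointwise
  (`average_gait_cycle()`). Extremum timings of the mean cycles are
  compared via `peak_delay_ms()`, which converts a gait-percent difference
  to the nearest integer millisecond at the mean stride time. Range
  recovery and peak shortfall come from `range_metrics()`.

For synthetic data the stride events are the phase-wrap ticks of the
generator — exact ground truth, so no heel-strike detector is needed. For
real recordings, heel-strike indices must be supplied with the trial;
event detection is deliberately out of scope.

## What the synthetic generator emulates — and what it does not

`make_gait_profile()` draws periodic joint trajectories as truncated
Fourier series (default 4 harmonics) in normalized gait phase, with
velocities as exact analytic derivatives times the instantaneous stride
rate. Stride times are Gaussian per stride: 1.2 ± 0.1 s for the
comfortable-speed class, 1.0 ± 0.2 s for the fast class. Default ranges of
motion are 65° (knee) and 20° (ankle) — values consistent with the
error-to-percent ratios characteristic of prosthetic level-ground walking —
scaled by 1.15 for the fast class, since faster walking recruits larger
excursions. The same seed yields the same harmonic shapes for both speed
classes: one subject, two speeds.

`make_echo_model()` places 3 Gaussian echo pulses (σ = 15 samples) per
channel at baseline depths in the usable span, modulates each pulse's depth
by ±0.25 cm in proportion to one joint variable (normalized to [−1, 1] by
its reference-cycle range and clamped), attenuates amplitude exponentially
with depth, and adds a DC offset and Gaussian sample noise (sd 0.02
relative to unit echo amplitude). On the fast trials the larger true
excursions drive the couplings into their clamped region — the synthetic
analogue of echo configurations never seen during training, which is what
degrades fast-set predictions directionally.

Deliberately **not** modeled: tissue acoustics (speed-of-sound variation,
time-gain compensation), socket–limb interaction forces, sensor lift-off,
muscle fatigue, and any biomechanically validated muscle geometry. Passing
tests on this generator therefore demonstrate that the pipeline's
arithmetic, plumbing and learning machinery are correct and that the
method recovers kinematics *when the echoes genuinely encode them*; they do
not certify performance on real residual-limb recordings.

## Problem sizes and numerical choices

The default experiment (`run_experiment(experiment_config(seed = 1))`)
simulates four 8 s trials (640 ticks each, ~1274 pooled training rows —
the same order of magnitude as a set of 10 m walking trials), trains the
four regressors and evaluates both testing sets in well under a minute on
one CPU; the test suite uses shorter trials and reduced iteration caps
where full fits are not the point. Ties and degenerate inputs are handled
by named, classed errors: wrong frame length, even envelope windows,
inconsistent geometry, tick discontinuities, missing trial roles, constant
signals in nRMSE, cutoffs at or above Nyquist, and fewer than two stride
events all fail loudly rather than silently.

## Known limitations

- The generator's feature–kinematics relationship is intentionally strong;
  real A-mode SNR, sensor migration and inter-subject variability will
  yield higher errors than synthetic runs.
- The round-robin staleness model assumes a strict 4-cycle; dropped frames
  are not simulated.
- Peak-timing comparisons use the argmax of the 101-point mean cycle, so
  timing resolution is 1% of a stride; `peak_delay_ms()` rounds to the
  nearest integer millisecond.
- Only intra-subject models are supported, by design: features depend on
  individual sensor placement and residual-limb anatomy.
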