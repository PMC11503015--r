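---
title: "Methods: synthetic gait sessions, EMG features and the multi-branch network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait sessions, EMG features and the multi-branch network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgait)
```

## The problem

Lower-limb exoskeletons and rehabilitation robots need the user's motion
intention before the motion happens. Surface electromyography (sEMG) leads
the mechanical action, so a model that maps an 8-channel sEMG window to (a)
the current walking phase — swing (SW), initial contact (IC), mid stance
(MSt), terminal stance (TSt) — and (b) the continuous hip, knee and ankle
angles can drive such a controller. `emgait` implements that mapping end to
end: a synthetic session generator, signal conditioning, two feature
representations, a three-branch CNN–GRU network trained jointly on both
tasks, and the evaluation suite.

## The synthetic session generator

No public recordings exist for this task, so the package ships a generator
whose defaults define the study conditions used throughout the tests:

* **Geometry.** 200 cycles of nominally 1 s (ordinary treadmill walking at
  roughly 4 km/h) sampled at 1.5 kHz, phase fractions SW 40% / IC 20% /
  MSt 20% / TSt 20%. Per-cycle durations get ±5% multiplicative jitter so a
  model cannot learn a fixed period; the jittered durations are renormalized
  so the total sample count is exact.
* **sEMG.** Each channel is band-limited Gaussian noise (20–150 Hz, the
  dominant physiological sEMG band, chosen inside the 20–300 Hz conditioning
  pass-band), normalized to unit RMS and amplitude-modulated by a
  phase-dependent activation envelope. The default activation matrix encodes
  the physiology: thigh muscles (RF, VLO, VMO, BF, ST) high in SW/IC, calf
  muscles (TIA, LGA, MGA) high in IC/MSt/TSt. Envelopes are raised-cosine
  smoothed over 10% of the adjoining phase lengths because real amplitude
  transitions are gradual. 50 Hz mains interference (amplitude 0.1) and
  white measurement noise (SD 0.05) are added — "moderate noise" relative to
  the unit-RMS carrier.
* **Footswitches.** Right-foot heel/metatarsal/toe switches follow a fixed
  phase→contact map (SW: airborne; IC: heel only; MSt: heel + forefoot;
  TSt: forefoot + toe), with 5 ms contact ramps, per-edge uniform timing
  jitter (±5 ms default) and additive noise, so recovering labels from
  pressure is non-trivial. The left foot is the right pattern shifted half a
  cycle.
* **Angles.** One fixed two-harmonic waveform per joint, phase-locked to the
  cycle and affinely mapped into the configured ranges (hip −15°…30°, knee
  −12°…45°, ankle −20°…8°). Only the ranges are prescribed, not waveforms;
  the two-harmonic shapes place the hip flexion peak at late swing, the knee
  flexion peak mid-swing and ankle plantarflexion at push-off, which is the
  canonical gait pattern. A slowly varying random gain (smoothed white
  noise squashed into [0.92, 1]) makes realizations differ across seeds
  while guaranteeing every sample stays in range; `angle_amplitude = 0`
  collapses to the mid-range constant.

What the generator deliberately does **not** model: motor-unit-level EMG
physiology, electrode artifacts, muscle fatigue, inter-subject variability,
or non-walking activities. Passing tests on this data certify the pipeline's
mechanics and learnability under the stated statistical structure, not
performance on real subjects.

A structural consequence worth knowing: within the flat interior of the
600-sample swing phase the envelope carries no position information, so a
320-sample window wholly inside it cannot resolve where in swing it sits.
About a fifth of windows see no envelope transition at all, and the knee —
whose 57° flexion peak with the steepest slopes falls mid-swing — is the
joint most exposed to that ambiguity. Even a regressor handed the true
label sequence (perfect envelope decoding) cannot push knee RMSE below
about 4.5° under the default conditions, and with the stochastic carrier
the practically attainable figure is higher; the evaluation consistently
shows the knee as the hardest joint by a factor of ~3 over the hip.

## Preprocessing

Second-order Butterworth filters: 20–300 Hz band-pass, then 49–51 Hz
band-stop (the order of the two stages commutes only approximately; this
order is fixed and documented). Offline processing uses zero-phase
forward–backward filtering (no phase lag; magnitude response squared) with
reflective padding of three coefficient spans; a causal single pass is
available for streaming use. `butterworth_response()` exposes the analytic
transfer-function magnitude, which the tests use as the oracle for measured
tone attenuation.

Zero standardization uses the sample (N−1) standard deviation per channel
per recording — that denominator is the documented contract — and refuses
zero-variance channels by name.

Footswitch labelling: channels are moving-average smoothed (20 ms), then
thresholded at 50% of each channel's 95th percentile (robust to outliers and
baseline noise; the threshold is configurable). The contact pattern maps to
phases via the rule table above, and the stream is debounced by merging any
run shorter than 50 ms into its predecessor, which also enforces the cyclic
SW→IC→MSt→TSt order on clean data.

## Features

Windows are 320 samples (213 ms) with stride 160 (50% overlap, the common
sEMG convention). 320 is the unique length for which the 64-point / 32-hop
STFT yields exactly 9 frames, matching the 9 × 9 × 8 spectrogram contract
(the alternative reading of "6 time periods" is inconsistent with that
matrix and was not adopted). Window labels use the majority rule (ties
resolved toward the lower phase code, deterministically); the regression
target is the angle at the window's **final** sample — the model predicts
the current state, not a window average.

The time-domain matrix is 5 × 8 with fixed row order WL, MAV, VAR, RMS, ZC.
The zero-crossing threshold defaults to 0.01, i.e. 1% of the unit
post-standardization channel SD. The STFT uses a symmetric Hann window and
linear magnitude (not power, not dB; the scale is exposed in
`stft_config()`); of the 33 one-sided bins (0–750 Hz) the first 9 rows
(0–187.5 Hz) are retained, since sEMG energy concentrates below 200 Hz.

## The network

* **Branch 1 (raw window):** conv1d(width 3, stride 1, valid) → ReLU →
  max-pool(2) → conv1d → ReLU → max-pool(2), giving 320 → 318 → 159 → 157 →
  78 steps, then a 3-layer GRU; the final hidden state is the embedding.
* **Branch 2 (spectrogram):** one conv2d(3 × 3, stride 2, valid) → ReLU →
  2 × 2 max-pool → flatten (9 × 9 → 4 × 4 → 2 × 2 spatially). Depth is
  configurable; one block is the default.
* **Branch 3 (time-domain matrix):** 3-layer GRU over 5 steps of 8
  dimensions (features as time steps, channels as dimensions).

The embeddings are concatenated in that fixed order and feed two fully
separate heads: FC → ReLU → 4-way softmax for gait, FC → ReLU → 3 linear
outputs (degrees, unnormalized targets) for angles. Valid (unpadded)
convolution is used because the convolution's index range implies no
padding; ReLU and max-pooling are the defaults where only "nonlinear
activation" and "pooling" are prescribed. Widths (16/32 conv1d kernels, 16
conv2d kernels, GRU hidden 32, FC hidden 128) are free choices sized to
train on one CPU in minutes; all are exposed in `model_config()`. Doubling
the GRU width or halving the window stride roughly doubles training time
for marginal held-out gains, which is why the smaller settings ship as
defaults.

Training minimizes `CE + λ·MSE` with λ = 0.1, balancing a cross-entropy of
order 1 against squared-degree errors of order 100. Adam (lr 1e-3, batch
64) runs for up to 40 epochs with a step schedule halving the rate at 60%
and 85% of the budget; a 10% validation carve-out is scored every epoch and
the best-validation-loss weights are kept. The time-domain and spectrogram
inputs are element-wise z-scored with training-set statistics stored inside
the model (raw windows are already standardized per recording). All
forward and backward passes are written in plain R against BLAS
matrix products; gradients are verified against central finite differences
in the test suite.

## Splitting and metrics

Windows overlap, so a plain random split leaks test information into
training through shared samples. The default split therefore groups whole
gait cycles (a window belongs to the cycle containing its final sample) and
assigns cycles to the 80% training / 20% test sides. Ungrouped and
gait-stratified splits are available for non-overlapping windows.

Classification metrics come from the 4 × 4 confusion matrix: per-class
precision and sensitivity, accuracy, and the macro (unweighted class mean)
and micro (pooled counts) averages PMAP/PMIP/PMAS/PMIS. Note the reporting
convention: the "macro/micro average accuracy" rows of the published-style
report are macro/micro averaged **precision**; for single-label multiclass
data micro precision = micro sensitivity = accuracy, an identity the tests
assert. A class never predicted has undefined precision; it is reported as
0 with a warning.

Regression metrics are per-joint RMSE in degrees and the zero-lag Pearson
correlation between predicted and true angle series ("cross-correlation
coefficient"; the maximum-over-lags reading was not adopted). Relative
error is RMSE divided by the observed true range of motion, in percent —
no published denominator reproduces the printed relative errors from the
printed RMSEs, so this convention is fixed and documented.

## Problem sizes and numerical choices

The full-scale property check trains on the default 200-cycle session
(~1 900 windows, ~56 k parameters, 40 epochs) and gates held-out gait
accuracy at ≥85%, per-joint RMSE at ≤5° and per-joint correlation at
≥0.90; unit tests use 6–20 cycle sessions and a deliberately small network
(GRU hidden 8). Softmax is computed with the max-subtraction trick;
probabilities are floored at 1e-12 inside the log; max-pool backward breaks
ties toward the earlier element; Adam uses the standard bias correction.
Determinism is via R's RNG only — identical configuration and seed
reproduce sessions, weights, curves and reports bit for bit.

## Limitations

The generator's envelope model makes gait classification from amplitude
features comparatively easy; real sEMG has heavier-tailed, non-stationary
modulation and cross-talk between channels. Angle prediction accuracy here
is bounded by the mid-swing ambiguity discussed above rather than by sensor
physics. Results on this synthetic benchmark therefore validate the
machinery and the training dynamics, and are not comparable to real-subject
accuracy figures.
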