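# emgait

Gait-phase recognition and continuous joint-angle estimation from surface
electromyography (sEMG), for people building motion-intent interfaces —
lower-limb exoskeleton and rehabilitation-robot controllers, prosthetics
research, movement-science labs.

## What it does

Walking is segmented into four phases — swing (SW), initial contact (IC),
mid stance (MSt), terminal stance (TSt) — and the controller needs, at any
moment, the current phase plus the hip/knee/ankle angles, decoded from
8 muscle channels (RF, VLO, VMO, BF, ST, TIA, LGA, MGA) sampled at 1.5 kHz.
`emgait` implements the full pipeline:

1. **Synthetic session generator** — no public recordings exist for this
   task, so the package ships a generator with phase-locked muscle
   activation envelopes over band-limited Gaussian carriers, 50 Hz mains
   interference, footswitch plantar-pressure traces and smooth joint-angle
   trajectories (hip −15…30°, knee −12…45°, ankle −20…8°).
2. **Preprocessing** — second-order Butterworth 20–300 Hz band-pass and
   49–51 Hz band-stop (zero-phase by default), per-channel zero
   standardization (sample SD), footswitch threshold labelling of the four
   phases with 50 ms debouncing.
3. **Features** per 320-sample window: the classical 5 × 8 time-domain
   matrix — waveform length, mean absolute value, variance, RMS,
   thresholded zero crossings per channel — and a 9 × 9 × 8 STFT magnitude
   spectrogram (64-point Hann frames, hop 32, rows 0–187.5 Hz retained).
4. **Multi-branch CNN–GRU network** (hand-written forward/backward passes,
   gradient-checked): a 1-D conv + 3-layer GRU branch on the raw window, a
   2-D conv branch on the spectrogram, a 3-layer GRU branch on the
   time-domain matrix; fused embeddings feed a 4-way softmax gait head and
   a 3-output linear angle head, trained jointly with
   `CE + 0.1 · MSE` by Adam.
5. **Evaluation** — confusion-matrix metrics with macro/micro averaged
   precision and sensitivity (PMAP/PMIP/PMAS/PMIS), per-joint RMSE in
   degrees, zero-lag cross-correlation and relative error.

See `vignettes/emgait-methods.Rmd` for the model, its assumptions and every
tunable parameter.

## Worked example

```r
library(emgait)

cfg <- sim_config(seed = 1)                     # 200 one-second cycles, 1.5 kHz
rec <- generate_session(cfg)

semg <- preprocess_semg(rec$semg, rec$sampling_rate)
rec2 <- emgait:::new_gait_recording(semg, rec$pressure, rec$angles,
                                    rec$labels, rec$sampling_rate)
feats <- featurize_recording(rec2)              # 1874 windows

sp <- split_windows(feats, 0.8, group_by_cycle = TRUE, seed = 1)
model <- emg_model(model_config(), seed = 1)
model <- train_model(model, sp$train, epochs = 40, seed = 1)
evaluate_model(model, sp$test)
```

```
<eval_report> 375 test windows
  gait accuracy 95.47% | PMAP 95.35 PMIP 95.47 PMAS 94.86 PMIS 95.47
  per-class precision (%): SW=96.6 IC=97.3 TSt=97.1 MSt=90.4
  hip   RMSE 2.09 deg, xcorr 0.991, rel err 4.7%
  knee  RMSE 6.76 deg, xcorr 0.918, rel err 11.9%
  ankle RMSE 3.51 deg, xcorr 0.903, rel err 12.6%
```

Reading: on held-out gait cycles the network identifies the walking phase
correctly 95% of the time (micro precision = micro sensitivity = accuracy
for single-label multiclass — the identity is asserted in the tests), and
tracks the joint angles with ~2–7° error at correlations ≥ 0.90. The knee
is hardest by design of the conditions: its flexion peak falls mid-swing,
where windows that see no envelope transition carry no cycle-position
information (the methods vignette quantifies this floor). Training takes
about five minutes on one CPU.

The same pipeline is scriptable from the shell:

```sh
emgait e2e --seed 1 --out results/        # or: Rscript exec/emgait e2e ...
emgait simulate --config my.yaml --out session.csv
```

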