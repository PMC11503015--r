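Package: emgait
Title: Gait Phase Recognition and Joint-Angle Estimation from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete pipeline that maps 8-channel surface electromyography
    (sEMG) recorded during walking to a four-class gait phase (swing, initial
    contact, mid stance, terminal stance) and to continuous hip, knee and
    ankle joint angles. Includes a synthetic gait-session generator
    (phase-modulated band-limited EMG, footswitch plantar-pressure traces,
    smooth joint-angle trajectories), Butterworth band-pass/band-stop
    preprocessing with zero standardization, footswitch-threshold gait
    labelling, classical time-domain EMG features (waveform length, mean
    absolute value, variance, RMS, thresholded zero crossings) and Hann-window
    short-time Fourier spectrograms, a hand-written multi-branch CNN-GRU
    network trained jointly on classification and regression, and a full
    evaluation suite (confusion-matrix metrics with macro/micro averaging,
    per-joint RMSE and zero-lag cross-correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
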