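test_that("windowing arithmetic and label rules are exact", {
  cfg <- sim_config(sampling_rate = 1000, n_cycles = 1, cycle_duration = 1,
                    cycle_jitter = 0, seed = 1)
  rec <- generate_session(cfg)
  wins <- segment_recording(rec, window_spec(320, 160))
  expect_length(wins, 5L)   # floor((1000 - 320)/160) + 1
  # a window that is 60% MSt under the majority rule is labelled MSt
  codes <- as.integer(rec$labels)
  w3 <- wins[[3]]
  frac <- mean(codes[w3$start:w3$end] == w3$gait)
  expect_gte(frac, 0.5)
  # angle target is the angle at the window's final sample
  expect_equal(w3$angles, rec$angles[w3$end, ])
})

test_that("stride equal to length tiles the recording without overlap", {
  rec <- small_session()
  wins <- segment_recording(rec, window_spec(320, 320))
  idx <- unlist(lapply(wins, function(w) w$start:w$end))
  expect_false(any(duplicated(idx)))
  expect_identical(diff(vapply(wins, `[[`, integer(1), "start")),
                   rep(320L, length(wins) - 1L))
})

test_that("a majority-MSt window is labelled MSt", {
  lab <- emgait:::new_gait_labels(
    c(rep(gait_phases()[["SW"]], 128), rep(gait_phases()[["MSt"]], 192)),
    1500)
  rec <- emgait:::new_gait_recording(matrix(stats::rnorm(320 * 8), 320, 8),
                                     matrix(0.5, 320, 8),
                                     matrix(0, 320, 3), lab, 1500)
  wins <- segment_recording(rec, window_spec(320, 320))
  expect_identical(wins[[1]]$gait, gait_phases()[["MSt"]])
})

test_that("time-domain features match hand-computed examples", {
  expect_equal(wave_length(c(0, 1, 0, 1)), 3)
  expect_equal(wave_length(rep(2, 10)), 0)
  expect_equal(signal_variance(c(1, -1, 1, -1)), 4 / 3)
  expect_equal(signal_variance(rep(3, 5)), 0)
  expect_equal(mean_absolute_value(c(1, -1, 1, -1)), 1)
  expect_equal(root_mean_square(c(3, 4)), sqrt(12.5))
  expect_equal(root_mean_square(rep(-2, 7)), 2)
  expect_identical(zero_crossings(c(1, -1, 1, -1), 0), 3L)
  expect_identical(zero_crossings(c(1, -1, 1, -1), 3), 0L)
  expect_identical(zero_crossings(c(1, 2, 3), 0), 0L)
})

test_that("features scale as expected and reject degenerate input", {
  set.seed(5)
  y <- stats::rnorm(50)
  expect_equal(wave_length(-2.5 * y), 2.5 * wave_length(y))
  expect_gte(root_mean_square(y)^2,
             signal_variance(y) * (length(y) - 1) / length(y) - 1e-12)
  expect_error(wave_length(1), "at least 2")
  expect_error(zero_crossings(c(1, -1), -0.1), "nonnegative")
})

test_that("features agree with brute-force loop oracles", {
  set.seed(6)
  for (k in 1:100) {
    y <- stats::rnorm(sample(10:200, 1))
    eps <- stats::runif(1, 0, 0.5)
    expect_equal(wave_length(y), oracle_wl(y), tolerance = 1e-12)
    expect_equal(mean_absolute_value(y), oracle_mav(y), tolerance = 1e-12)
    expect_equal(signal_variance(y), oracle_var(y), tolerance = 1e-12)
    expect_equal(root_mean_square(y), oracle_rms(y), tolerance = 1e-12)
    expect_identical(zero_crossings(y, eps), oracle_zc(y, eps))
  }
})

test_that("the time-domain matrix is 5 x 8 in the documented row order", {
  set.seed(7)
  raw <- matrix(stats::rnorm(320 * 8), 320, 8,
                dimnames = list(NULL, semg_channels()))
  td <- time_domain_matrix(raw, eps = 0.01)
  expect_identical(dim(td), c(5L, 8L))
  expect_identical(rownames(td), td_feature_names())
  expect_true(all(time_domain_matrix(matrix(0, 320, 8)) == 0))
  # column j equals the five scalar features of channel j alone
  j <- 4L
  expect_equal(unname(td[, j]),
               c(wave_length(raw[, j]), mean_absolute_value(raw[, j]),
                 signal_variance(raw[, j]), root_mean_square(raw[, j]),
                 zero_crossings(raw[, j], 0.01)))
})

test_that("the STFT spectrogram has the contracted geometry", {
  cfg <- stft_config()
  bins <- stft_bins(cfg, fs = 1500)
  expect_identical(bins$n_bins, 33L)
  expect_equal(bins$freqs, (0:8) * 1500 / 64)
  expect_equal(bins$freqs[9], 187.5)
  sp <- stft_spectrogram(matrix(stats::rnorm(320 * 8), 320, 8), cfg)
  expect_identical(dim(sp), c(9L, 9L, 8L))
  expect_true(all(stft_spectrogram(matrix(0, 320, 8), cfg) == 0))
  expect_error(stft_spectrogram(matrix(0, 32, 8), cfg), "shorter")
  # the full one-sided transform of a real frame has 33 bins
  frame <- stats::fft(stats::rnorm(64))
  expect_identical(length(frame[seq_len(64 %/% 2 + 1)]), 33L)
})

test_that("a pure bin-center tone concentrates energy in its row", {
  fs <- 1500
  tone <- sin(2 * pi * 46.875 * (0:319) / fs)   # center of bin index 2
  raw <- matrix(0, 320, 8)
  raw[, 3] <- tone
  sp <- stft_spectrogram(raw, stft_config())
  e_row <- rowSums(sp[, , 3]^2)
  # the Hann main lobe spans the center bin plus one neighbour on each side:
  # the tone's row is the maximum and the three rows hold ~all the energy
  expect_identical(which.max(e_row), 3L)
  expect_gte(e_row[3] / sum(e_row), 0.60)
  expect_gte(sum(e_row[2:4]) / sum(e_row), 0.99)
  expect_true(all(sp[, , -3] == 0))
})

test_that("retained rows hold the energy of a band-limited signal", {
  fs <- 1500
  tt <- (0:319) / fs
  x <- sin(2 * pi * 40 * tt) + 0.7 * sin(2 * pi * 80 * tt) +
    0.4 * sin(2 * pi * 120 * tt)
  cfg <- stft_config()
  sp9 <- stft_spectrogram(matrix(x, ncol = 1), cfg)[, , 1]
  # Parseval oracle: per-frame windowed time-domain energy
  w <- emgait:::hann_window(64)
  e_time <- 0
  for (f in 1:9) {
    seg <- x[((f - 1) * 32 + 1):((f - 1) * 32 + 64)] * w
    e_time <- e_time + sum(seg^2)
  }
  e_freq <- (sp9[1, ]^2 + 2 * colSums(sp9[-1, ]^2)) / 64
  expect_lt(abs(sum(e_freq) - e_time) / e_time, 0.05)
})

test_that("interior frames agree with an independent STFT implementation", {
  set.seed(8)
  x <- stats::rnorm(320)
  mine <- stft_spectrogram(matrix(x, ncol = 1), stft_config())[, , 1]
  ref <- signal::specgram(x, n = 64, Fs = 1500,
                          window = emgait:::hann_window(64), overlap = 32)
  # specgram drops the Nyquist bin and the final frame; compare the overlap
  expect_equal(unname(mine[1:9, 1:8]), unname(Mod(ref$S[1:9, 1:8])),
               tolerance = 1e-10)
})

test_that("featurize fills every representation consistently", {
  feats <- small_features()
  expect_s3_class(feats, "emg_features")
  expect_identical(dim(feats$td)[-1], c(5L, 8L))
  expect_identical(dim(feats$spec)[-1], c(9L, 9L, 8L))
  expect_true(all(is.finite(feats$td)))
  expect_true(all(is.finite(feats$spec)))
  k <- 7L
  expect_equal(feats$td[k, , ],
               unname(time_domain_matrix(feats$raw[k, , ], eps = 0.01)),
               tolerance = 1e-12)
  # feature store round-trip
  path <- file.path(tempdir(), "feats_rt.rds")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(back$spec, feats$spec)
  unlink(c(path, paste0(path, ".json")))
})
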