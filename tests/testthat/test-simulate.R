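test_that("phase sequence splits the cycle by the configured fractions", {
  cfg <- sim_config(sampling_rate = 1000, n_cycles = 1, cycle_duration = 1,
                    cycle_jitter = 0, seed = 1)
  lab <- generate_phase_sequence(cfg)
  r <- rle(as.integer(lab))
  p <- gait_phases()
  expect_identical(r$values, unname(p[c("SW", "IC", "MSt", "TSt")]))
  expect_identical(r$lengths, c(400L, 200L, 200L, 200L))
  expect_identical(length(lab), 1000L)
})

test_that("phase sequence is deterministic under a fixed seed", {
  cfg <- sim_config(n_cycles = 3, seed = 11)
  expect_identical(generate_phase_sequence(cfg), generate_phase_sequence(cfg))
})

test_that("each requested cycle produces exactly one swing onset", {
  cfg <- sim_config(n_cycles = 10, cycle_duration = 0.4, seed = 3)
  codes <- as.integer(generate_phase_sequence(cfg))
  sw <- gait_phases()[["SW"]]
  onsets <- sum(codes == sw & c(TRUE, codes[-length(codes)] != sw))
  expect_identical(onsets, 10L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cycles = 0), "n_cycles")
  expect_error(sim_config(cycle_duration = -1), "cycle_duration")
  expect_error(sim_config(phase_fractions = c(0.5, 0.2, 0.2, 0.2)),
               "phase_fractions")
  expect_error(sim_config(emg_band = c(20, 900)), "Nyquist")
})

test_that("generated angles always respect the configured ranges", {
  set.seed(1)
  for (k in 1:30) {
    rng <- cbind(-stats::runif(3, 5, 30), stats::runif(3, 5, 50))
    cfg <- sim_config(n_cycles = 2, cycle_duration = 0.5,
                      angle_ranges = rng, seed = k)
    ang <- generate_angles(generate_phase_sequence(cfg), cfg)
    for (j in 1:3) {
      expect_gte(min(ang[, j]), rng[j, 1])
      expect_lte(max(ang[, j]), rng[j, 2])
    }
  }
})

test_that("default hip range matches the configured -15..30 degrees", {
  cfg <- sim_config(n_cycles = 4, seed = 2)
  ang <- generate_angles(generate_phase_sequence(cfg), cfg)
  expect_gte(min(ang[, "hip"]), -15)
  expect_lte(max(ang[, "hip"]), 30)
})

test_that("zero amplitude collapses angles to the mid-range constant", {
  cfg <- sim_config(n_cycles = 1, cycle_duration = 0.5, angle_amplitude = 0,
                    seed = 4)
  ang <- generate_angles(generate_phase_sequence(cfg), cfg)
  mids <- rowMeans(default_angle_ranges())
  for (j in 1:3)
    expect_equal(unname(ang[, j]), rep(unname(mids[j]), nrow(ang)))
})

test_that("different seeds give different in-range trajectories", {
  lab <- generate_phase_sequence(sim_config(n_cycles = 2, seed = 5))
  a1 <- generate_angles(lab, sim_config(n_cycles = 2, seed = 5))
  a2 <- generate_angles(lab, sim_config(n_cycles = 2, seed = 6))
  expect_false(isTRUE(all.equal(a1, a2)))
  expect_true(all(a1[, "knee"] >= -12 & a1[, "knee"] <= 45))
  expect_true(all(a2[, "knee"] >= -12 & a2[, "knee"] <= 45))
})

test_that("degenerate sEMG config reduces to pure measurement noise", {
  cfg <- sim_config(n_cycles = 80, sampling_rate = 1500, cycle_duration = 1,
                    activation_matrix = matrix(0, 8, 4), mains_amplitude = 0,
                    measurement_noise_sd = 0.3, seed = 7)
  lab <- generate_phase_sequence(cfg)
  x <- generate_semg(lab, cfg)
  expect_gte(nrow(x), 1e5)
  rms <- sqrt(colMeans(x^2))
  expect_true(all(abs(rms - 0.3) / 0.3 < 0.1))
})

test_that("tibialis RMS is higher in mid stance than in swing", {
  rec <- small_session()
  codes <- as.integer(rec$labels)
  p <- gait_phases()
  tia <- rec$semg[, "TIA"]
  rms_mst <- sqrt(mean(tia[codes == p[["MSt"]]]^2))
  rms_sw <- sqrt(mean(tia[codes == p[["SW"]]]^2))
  expect_gt(rms_mst, rms_sw)
})

test_that("mains interference leaves a 50 Hz periodogram peak", {
  rec <- small_session()
  fs <- rec$sampling_rate
  x <- rec$semg[, "RF"]
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  at <- function(f) pw[which.min(abs(freq - f))]
  expect_gt(at(50), at(45))
  expect_gt(at(50), at(55))
})

test_that("per-phase mean envelope tracks the activation matrix", {
  cfg <- sim_config(n_cycles = 100, seed = 8)
  lab <- generate_phase_sequence(cfg)
  env <- attr(generate_semg(lab, cfg), "envelope")
  codes <- as.integer(lab)
  p <- gait_phases()
  act <- cfg$activation_matrix
  for (ph in colnames(act)) {
    sel <- codes == p[[ph]]
    got <- colMeans(env[sel, , drop = FALSE])
    expect_true(all(abs(got - act[, ph]) < 0.05),
                info = paste("phase", ph))
  }
})

test_that("swing has no right-foot ground contact", {
  cfg <- sim_config(n_cycles = 4, pressure_noise_sd = 0, edge_jitter_s = 0,
                    seed = 9)
  lab <- generate_phase_sequence(cfg)
  pr <- generate_pressure(lab, cfg)
  codes <- as.integer(lab)
  # interior of swing (transition ramps excluded)
  sw_runs <- rle(codes == gait_phases()[["SW"]])
  ends <- cumsum(sw_runs$lengths)
  interior <- unlist(lapply(which(sw_runs$values), function(k) {
    i0 <- ends[k] - sw_runs$lengths[k] + 1L
    (i0 + 30L):(ends[k] - 30L)
  }))
  expect_lt(max(pr[interior, 1:4]), 0.5)
})

test_that("heel duty cycle approximates the IC plus MSt time fraction", {
  cfg <- sim_config(n_cycles = 20, seed = 10)
  lab <- generate_phase_sequence(cfg)
  pr <- generate_pressure(lab, cfg)
  duty <- mean(pr[, "heel_R"] > 0.5)
  p <- gait_phases()
  want <- mean(as.integer(lab) %in% c(p[["IC"]], p[["MSt"]]))
  expect_lt(abs(duty - want), 0.03)
})

test_that("sessions are reproducible and pass the recording invariants", {
  cfg <- sim_config(n_cycles = 3, seed = 21)
  r1 <- generate_session(cfg)
  r2 <- generate_session(cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_silent(validate_recording(r1))
  # total length is exact despite per-cycle jitter
  cfg2 <- sim_config(n_cycles = 20, seed = 22)
  expect_identical(nrow(generate_session(cfg2)$semg), 30000L)
})

test_that("recording round-trips through the CSV container", {
  rec <- generate_session(sim_config(n_cycles = 2, seed = 13))
  path <- file.path(tempdir(), "rt_session.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$semg, rec$semg, tolerance = 1e-12)
  expect_equal(back$angles, rec$angles, tolerance = 1e-12)
  expect_identical(as.integer(back$labels), as.integer(rec$labels))
  expect_equal(back$sampling_rate, rec$sampling_rate)
  unlink(c(path, paste0(path, ".json")))
})
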