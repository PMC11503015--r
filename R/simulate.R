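# Synthetic walking-session generator.  Every generator derives its RNG
# stream from cfg$seed plus a fixed offset so that generate_session() and the
# individual generators are reproducible and mutually independent.

seed_offset <- function(cfg, k) as.integer((cfg$seed %% 1000000L) * 101L + k)

#' Generate a per-sample gait-phase label sequence
#'
#' Produces the periodic SW -> IC -> MSt -> TSt phase stream for `n_cycles`
#' walking cycles.  Per-cycle durations receive multiplicative jitter
#' (`cfg$cycle_jitter`) and are then renormalized so the total length is
#' exactly `round(n_cycles * cycle_duration * sampling_rate)` samples.
#'
#' @param cfg A [sim_config()].
#' @return A `gait_labels` object: integer vector of phase codes (see
#'   [gait_phases()]) with attributes `sampling_rate`, `cycle_id` (1-based
#'   cycle index per sample) and `cycle_pos` (position within the cycle in
#'   `[0, 1)`).
#' @examples
#' lab <- generate_phase_sequence(sim_config(n_cycles = 2, seed = 1))
#' table(factor(lab, levels = 0:3, labels = gait_phase_names()))
#' @export
generate_phase_sequence <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(seed_offset(cfg, 1L))
  fs <- cfg$sampling_rate
  total_n <- round(cfg$n_cycles * cfg$cycle_duration * fs)
  dur <- cfg$cycle_duration *
    stats::runif(cfg$n_cycles, 1 - cfg$cycle_jitter, 1 + cfg$cycle_jitter)
  dur <- dur * (cfg$n_cycles * cfg$cycle_duration) / sum(dur)
  bounds <- round(c(0, cumsum(dur)) * fs)
  bounds[cfg$n_cycles + 1L] <- total_n

  codes <- integer(total_n)
  cycle_id <- integer(total_n)
  cycle_pos <- numeric(total_n)
  order_codes <- phase_cycle_order()           # SW, IC, MSt, TSt as codes
  frac <- cumsum(cfg$phase_fractions)
  for (k in seq_len(cfg$n_cycles)) {
    i0 <- bounds[k] + 1L
    i1 <- bounds[k + 1L]
    len <- i1 - i0 + 1L
    ph_len <- diff(c(0L, round(frac * len)))   # exact per-phase sample counts
    codes[i0:i1] <- rep(order_codes, ph_len)
    cycle_id[i0:i1] <- k
    cycle_pos[i0:i1] <- (seq_len(len) - 1) / len
  }
  new_gait_labels(codes, fs, cycle_id = cycle_id, cycle_pos = cycle_pos)
}

new_gait_labels <- function(codes, sampling_rate,
                            cycle_id = NULL, cycle_pos = NULL) {
  stopifnot(all(codes %in% gait_phases()))
  structure(as.integer(codes), sampling_rate = sampling_rate,
            cycle_id = cycle_id, cycle_pos = cycle_pos,
            class = "gait_labels")
}

#' @export
print.gait_labels <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:3, labels = gait_phase_names()))
  cat(sprintf("<gait_labels> %d samples at %g Hz\n", length(x),
              attr(x, "sampling_rate")))
  print(tab)
  invisible(x)
}

# Position within the cycle for every sample.  Simulated labels carry it as
# an attribute; otherwise it is reconstructed from SW onsets.
label_cycle_pos <- function(labels) {
  pos <- attr(labels, "cycle_pos")
  if (!is.null(pos)) return(pos)
  codes <- as.integer(labels)
  sw <- gait_phases()[["SW"]]
  onsets <- which(codes == sw & c(TRUE, codes[-length(codes)] != sw))
  bounds <- unique(c(1L, onsets, length(codes) + 1L))
  pos <- numeric(length(codes))
  for (k in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[k]; i1 <- bounds[k + 1L] - 1L
    pos[i0:i1] <- (seq_len(i1 - i0 + 1L) - 1) / (i1 - i0 + 1L)
  }
  pos
}

# Canonical two-harmonic waveforms on cycle position phi in [0,1), one per
# joint, later affinely mapped into the configured range.  Shapes place the
# hip flexion peak at late swing, the knee flexion peak mid-swing and ankle
# plantarflexion at push-off.
joint_shape <- function(joint, phi) {
  switch(joint,
    hip   = 0.95 * cos(2 * pi * (phi - 0.32)) + 0.20 * cos(4 * pi * (phi - 0.10)),
    knee  = 0.80 * cos(2 * pi * (phi - 0.20)) + 0.50 * cos(4 * pi * (phi - 0.15)),
    ankle = 0.60 * cos(2 * pi * (phi - 0.55)) + 0.45 * cos(4 * pi * (phi - 0.35)),
    stop("unknown joint: ", joint))
}

# shape normalized to [-1, 1] using its global extrema (fine-grid constants)
joint_shape_unit <- function(joint, phi) {
  grid <- joint_shape(joint, seq(0, 1, length.out = 4096L))
  lo <- min(grid); hi <- max(grid)
  2 * (joint_shape(joint, phi) - lo) / (hi - lo) - 1
}

#' Generate smooth joint-angle trajectories
#'
#' Hip, knee and ankle angles over the labelled session: a fixed two-harmonic
#' waveform per joint, phase-locked to the gait cycle, scaled into the
#' configured range and modulated by a slowly varying random gain (so
#' realizations differ across seeds while every sample stays inside its
#' range).  `angle_amplitude = 0` yields constant mid-range angles.
#'
#' @param labels A `gait_labels` series (normally from
#'   [generate_phase_sequence()]).
#' @param cfg A [sim_config()].
#' @return Numeric matrix, samples x 3, columns `hip`, `knee`, `ankle`
#'   (degrees).
#' @export
generate_angles <- function(labels, cfg) {
  validate_sim_config(cfg)
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  set.seed(seed_offset(cfg, 2L))
  n <- length(labels)
  phi <- label_cycle_pos(labels)
  out <- matrix(0, n, 3L, dimnames = list(NULL, joint_names()))
  # smooth gain in [0.92, 1]: heavily smoothed white noise squashed by tanh
  win <- max(1L, round(0.5 * cfg$sampling_rate))
  for (j in seq_len(3L)) {
    joint <- joint_names()[j]
    lo <- cfg$angle_ranges[j, 1]; hi <- cfg$angle_ranges[j, 2]
    mid <- (lo + hi) / 2; half <- (hi - lo) / 2
    g <- moving_average(stats::rnorm(n), win)
    g <- 1 - 0.04 * (1 + tanh(g / stats::sd(g)))
    out[, j] <- mid + cfg$angle_amplitude * half * g *
      joint_shape_unit(joint, phi)
  }
  out
}

# centered moving average, edges handled by shrinking the window
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- window %/% 2L
  i0 <- pmax(seq_len(n) - half, 1L)
  i1 <- pmin(seq_len(n) + (window - half - 1L), n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

# step envelope from the activation matrix with raised-cosine transitions;
# each boundary blends over 10% of the shorter neighbouring phase on each side
activation_envelope <- function(codes, activation) {
  n <- length(codes)
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  env <- matrix(0, n, 8L)
  # activation columns are in temporal order SW/IC/MSt/TSt; map phase codes
  # (whose numeric order is SW/IC/TSt/MSt) onto those columns by name
  col_of_code <- match(gait_phase_names(), c("SW", "IC", "MSt", "TSt"))
  for (ch in seq_len(8L)) {
    lev <- activation[ch, col_of_code[r$values + 1L]]
    e <- rep(lev, r$lengths)
    if (length(r$values) > 1L) {
      for (b in seq_len(length(r$values) - 1L)) {
        w <- floor(0.1 * min(r$lengths[b], r$lengths[b + 1L]))
        if (w < 1L) next
        idx <- (ends[b] - w + 1L):min(ends[b] + w, n)
        s <- seq_along(idx) / (length(idx) + 1L)
        blend <- 0.5 - 0.5 * cos(pi * s)       # raised cosine 0 -> 1
        e[idx] <- lev[b] + (lev[b + 1L] - lev[b]) * blend
      }
    }
    env[, ch] <- e
  }
  env
}

# white Gaussian noise band-limited to `band` Hz, normalized to unit RMS
bandlimited_noise <- function(n, band, fs) {
  bf <- signal::butter(2, band * 2 / fs, type = "pass")
  x <- signal::filter(bf, stats::rnorm(n + 2000L))
  x <- x[-seq_len(2000L)]                      # drop start-up transient
  x / stats::sd(x)
}

#' Generate the 8-channel sEMG block
#'
#' Per channel: a band-limited unit-RMS Gaussian carrier amplitude-modulated
#' by the raised-cosine-smoothed activation envelope of the current gait
#' phase, plus 50 Hz mains interference and white measurement noise.  The
#' default activation matrix puts the thigh muscles high in SW/IC and the
#' calf muscles high in IC/MSt/TSt.
#'
#' @inheritParams generate_angles
#' @return Numeric matrix, samples x 8, columns per [semg_channels()], with
#'   the noise-free modulation envelope attached as attribute `envelope`.
#' @export
generate_semg <- function(labels, cfg) {
  validate_sim_config(cfg)
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  set.seed(seed_offset(cfg, 3L))
  n <- length(labels)
  fs <- cfg$sampling_rate
  env <- activation_envelope(as.integer(labels), cfg$activation_matrix)
  tt <- (seq_len(n) - 1) / fs
  out <- matrix(0, n, 8L, dimnames = list(NULL, semg_channels()))
  for (ch in seq_len(8L)) {
    carrier <- bandlimited_noise(n, cfg$emg_band, fs)
    mains <- cfg$mains_amplitude *
      sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
    out[, ch] <- env[, ch] * carrier + mains +
      cfg$measurement_noise_sd * stats::rnorm(n)
  }
  attr(out, "envelope") <- env
  out
}

# Phase -> right-foot contact map (rows SW/IC/MSt/TSt in code order index).
# SW: airborne; IC: heel only; MSt: heel + both metatarsals; TSt: forefoot
# and big toe without heel.  Must stay consistent with extract_gait_phases().
phase_contact_map <- function() {
  m <- matrix(0, 4L, 4L,
              dimnames = list(gait_phase_names(),
                              c("heel", "meta5", "meta1", "toe")))
  m["IC", ]  <- c(1, 0, 0, 0)
  m["MSt", ] <- c(1, 1, 1, 0)
  m["TSt", ] <- c(0, 1, 1, 1)
  m
}

# shift every run boundary of a 0/1 signal by an independent uniform jitter
jitter_edges <- function(x, max_shift) {
  if (max_shift < 1L) return(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  nb <- length(ends) - 1L
  if (nb < 1L) return(x)
  shift <- round(stats::runif(nb, -max_shift, max_shift))
  new_ends <- pmin(pmax(ends[seq_len(nb)] + shift, 1L), length(x) - 1L)
  new_ends <- cummax(new_ends)                 # keep boundaries ordered
  lens <- diff(c(0L, new_ends, length(x)))
  keep <- lens > 0L
  inverse.rle(structure(list(lengths = lens[keep], values = r$values[keep]),
                        class = "rle"))
}

#' Generate the plantar-pressure switch block
#'
#' Eight footswitch channels (right foot then left foot: heel, fifth
#' metatarsal, first metatarsal, big toe).  Right-foot contacts follow the
#' phase-to-contact map used by [extract_gait_phases()]; the left foot is the
#' same pattern shifted by half a cycle.  Contact edges receive uniform
#' timing jitter (`cfg$edge_jitter_s`), transitions a 5 ms half-cosine ramp,
#' and every channel additive Gaussian noise, so label recovery from the
#' pressure block is non-trivial under the defaults.
#'
#' @inheritParams generate_angles
#' @return Numeric matrix, samples x 8, columns per [pressure_channels()].
#' @export
generate_pressure <- function(labels, cfg) {
  validate_sim_config(cfg)
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  set.seed(seed_offset(cfg, 4L))
  n <- length(labels)
  fs <- cfg$sampling_rate
  codes <- as.integer(labels)
  cmap <- phase_contact_map()
  max_shift <- round(cfg$edge_jitter_s * fs)
  half_cycle <- round(cfg$cycle_duration * fs / 2)
  ramp_n <- max(1L, round(0.005 * fs))
  kernel <- signal::hanning(2L * ramp_n + 1L)    # symmetric 5 ms ramp
  kernel <- kernel / sum(kernel)

  out <- matrix(0, n, 8L, dimnames = list(NULL, pressure_channels()))
  phase_name <- gait_phase_names()[codes + 1L]
  for (sw in seq_len(4L)) {
    base <- as.numeric(cmap[phase_name, sw])
    base <- jitter_edges(base, max_shift)
    smooth <- as.numeric(stats::filter(base, kernel, sides = 2))
    smooth[is.na(smooth)] <- base[is.na(smooth)]
    out[, sw] <- smooth + cfg$pressure_noise_sd * stats::rnorm(n)
    left <- c(smooth[(half_cycle + 1L):n], smooth[seq_len(half_cycle)])
    out[, sw + 4L] <- left + cfg$pressure_noise_sd * stats::rnorm(n)
  }
  out
}

#' Generate a complete synchronized walking session
#'
#' Composes the label, sEMG, pressure and angle generators into one
#' [gait_recording]; fully reproducible from the configuration (including its
#' seed).
#'
#' @param cfg A [sim_config()].
#' @return A `gait_recording` with elements `semg` (samples x 8), `pressure`
#'   (samples x 8), `angles` (samples x 3), `labels` (`gait_labels`) and
#'   `sampling_rate`.
#' @examples
#' rec <- generate_session(sim_config(n_cycles = 2, seed = 3))
#' rec
#' @export
generate_session <- function(cfg) {
  validate_sim_config(cfg)
  labels <- generate_phase_sequence(cfg)
  semg <- generate_semg(labels, cfg)
  attr(semg, "envelope") <- NULL
  rec <- new_gait_recording(
    semg = semg,
    pressure = generate_pressure(labels, cfg),
    angles = generate_angles(labels, cfg),
    labels = labels,
    sampling_rate = cfg$sampling_rate,
    seed = cfg$seed)
  validate_recording(rec)
  rec
}
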