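#' Default phase-dependent muscle activation matrix
#'
#' Envelope amplitude (0..1) of each of the eight muscles in each of the four
#' gait phases.  Thigh muscles (RF, VLO, VMO, BF, ST) drive hip/knee motion
#' and are most active during swing and initial contact; calf muscles (TIA,
#' LGA, MGA) provide support and ankle torque and dominate initial contact,
#' mid stance and terminal stance.
#'
#' @return An 8 x 4 numeric matrix, rows named by [semg_channels()], columns
#'   `SW`, `IC`, `MSt`, `TSt`.
#' @export
default_activation_matrix <- function() {
  m <- rbind(
    RF  = c(0.80, 0.90, 0.20, 0.30),
    VLO = c(0.70, 0.80, 0.25, 0.20),
    VMO = c(0.75, 0.85, 0.20, 0.25),
    BF  = c(0.90, 0.60, 0.15, 0.20),
    ST  = c(0.85, 0.65, 0.20, 0.15),
    TIA = c(0.30, 0.90, 0.70, 0.50),
    LGA = c(0.15, 0.50, 0.80, 0.90),
    MGA = c(0.20, 0.55, 0.75, 0.85)
  )
  colnames(m) <- c("SW", "IC", "MSt", "TSt")
  m
}

#' Default joint-angle ranges (degrees)
#'
#' Range of motion over one walking cycle: hip -15..30, knee -12..45,
#' ankle -20..8 degrees.
#'
#' @return A 3 x 2 matrix with rows `hip`, `knee`, `ankle` and columns
#'   `min`, `max`.
#' @export
default_angle_ranges <- function() {
  m <- rbind(hip = c(-15, 30), knee = c(-12, 45), ankle = c(-20, 8))
  colnames(m) <- c("min", "max")
  m
}

#' Synthetic gait-session configuration
#'
#' Bundles every parameter of the synthetic walking-session generator.  The
#' defaults describe ordinary treadmill walking at roughly 4 km/h: 1 s gait
#' cycles sampled at 1.5 kHz, the phase split SW 40% / IC 20% / MSt 20% /
#' TSt 20%, and phase-dependent muscle activation per
#' [default_activation_matrix()].
#'
#' @param sampling_rate Sampling frequency in Hz (all channel blocks share it).
#' @param n_cycles Number of gait cycles to generate.
#' @param cycle_duration Nominal cycle duration in seconds.
#' @param phase_fractions Length-4 proportions of the cycle spent in SW, IC,
#'   MSt, TSt (temporal order); must sum to 1.
#' @param activation_matrix 8 x 4 matrix of envelope amplitudes in `[0, 1]`
#'   (muscles x phases SW/IC/MSt/TSt).
#' @param emg_band Length-2 Hz pair: pass band of the band-limited Gaussian
#'   carrier underlying the EMG interference pattern.
#' @param mains_amplitude Amplitude of the injected 50 Hz mains interference,
#'   in the same relative units as the unit-RMS carrier.
#' @param angle_ranges 3 x 2 matrix of per-joint angle ranges in degrees.
#' @param angle_amplitude Scale in `[0, 1]` applied to the angle excursion;
#'   0 yields constant mid-range angles.
#' @param measurement_noise_sd SD of additive white measurement noise on each
#'   sEMG channel.
#' @param pressure_noise_sd SD of additive noise on the footswitch channels.
#' @param edge_jitter_s Maximum random shift (seconds, uniform +/-) applied to
#'   each footswitch contact edge.
#' @param cycle_jitter Multiplicative per-cycle duration jitter (0.05 means
#'   +/-5%); total session length is renormalized to
#'   `n_cycles * cycle_duration`.
#' @param seed Integer seed making the whole session reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cycles = 2, seed = 7)
#' cfg$phase_fractions
#' @export
sim_config <- function(sampling_rate = 1500,
                       n_cycles = 200,
                       cycle_duration = 1.0,
                       phase_fractions = c(SW = 0.4, IC = 0.2,
                                           MSt = 0.2, TSt = 0.2),
                       activation_matrix = default_activation_matrix(),
                       emg_band = c(20, 150),
                       mains_amplitude = 0.1,
                       angle_ranges = default_angle_ranges(),
                       angle_amplitude = 1,
                       measurement_noise_sd = 0.05,
                       pressure_noise_sd = 0.05,
                       edge_jitter_s = 0.005,
                       cycle_jitter = 0.05,
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, n_cycles = n_cycles,
              cycle_duration = cycle_duration,
              phase_fractions = phase_fractions,
              activation_matrix = activation_matrix,
              emg_band = emg_band, mains_amplitude = mains_amplitude,
              angle_ranges = angle_ranges, angle_amplitude = angle_amplitude,
              measurement_noise_sd = measurement_noise_sd,
              pressure_noise_sd = pressure_noise_sd,
              edge_jitter_s = edge_jitter_s, cycle_jitter = cycle_jitter,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$n_cycles) || cfg$n_cycles <= 0)
    stop("configuration error: n_cycles must be positive", call. = FALSE)
  if (!is.numeric(cfg$cycle_duration) || cfg$cycle_duration <= 0)
    stop("configuration error: cycle_duration must be positive", call. = FALSE)
  if (length(cfg$phase_fractions) != 4L ||
      abs(sum(cfg$phase_fractions) - 1) > 1e-9)
    stop("configuration error: phase_fractions must be 4 proportions summing to 1",
         call. = FALSE)
  if (any(cfg$phase_fractions <= 0))
    stop("configuration error: phase_fractions must all be positive",
         call. = FALSE)
  if (!all(dim(cfg$activation_matrix) == c(8L, 4L)))
    stop("configuration error: activation_matrix must be 8 x 4", call. = FALSE)
  if (any(cfg$activation_matrix < 0) || any(cfg$activation_matrix > 1))
    stop("configuration error: activation amplitudes must lie in [0, 1]",
         call. = FALSE)
  if (length(cfg$emg_band) != 2L || cfg$emg_band[1] <= 0 ||
      cfg$emg_band[1] >= cfg$emg_band[2])
    stop("configuration error: emg_band must be an increasing positive Hz pair",
         call. = FALSE)
  if (cfg$sampling_rate <= 2 * max(cfg$emg_band))
    stop("configuration error: emg_band exceeds the Nyquist frequency",
         call. = FALSE)
  if (!all(dim(cfg$angle_ranges) == c(3L, 2L)) ||
      any(cfg$angle_ranges[, 1] >= cfg$angle_ranges[, 2]))
    stop("configuration error: angle_ranges must be 3 increasing degree pairs",
         call. = FALSE)
  if (cfg$angle_amplitude < 0 || cfg$angle_amplitude > 1)
    stop("configuration error: angle_amplitude must lie in [0, 1]",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d cycles of %.3g s at %g Hz (jitter +/-%g%%), seed %d\n",
              x$n_cycles, x$cycle_duration, x$sampling_rate,
              100 * x$cycle_jitter, x$seed))
  cat(sprintf("  phase fractions SW/IC/MSt/TSt: %s\n",
              paste(format(x$phase_fractions), collapse = " ")))
  cat(sprintf("  carrier band %g-%g Hz, mains %g, noise sd %g\n",
              x$emg_band[1], x$emg_band[2], x$mains_amplitude,
              x$measurement_noise_sd))
  invisible(x)
}
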