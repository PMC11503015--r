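# Windowing and the two feature representations: the 5 x 8 time-domain
# matrix (WL, MAV, VAR, RMS, ZC per channel) and the 9 x 9 x 8 STFT
# magnitude spectrogram.

#' Analysis-window specification
#'
#' The default 320-sample window (213 ms at 1.5 kHz) is the unique length for
#' which the 64-point / 32-hop STFT yields exactly 9 frames, matching the
#' 9 x 9 x 8 spectrogram contract.
#'
#' @param length_samples Window length in samples (>= 64 so one STFT frame
#'   fits).
#' @param stride_samples Hop between consecutive windows (default 50%
#'   overlap).
#' @param label_rule `"majority"` (most frequent phase in the window) or
#'   `"center"` (phase at the central sample).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length_samples = 320L, stride_samples = 160L,
                        label_rule = c("majority", "center")) {
  label_rule <- match.arg(label_rule)
  if (length_samples < 64L)
    stop("configuration error: window length must be >= 64 samples",
         call. = FALSE)
  if (stride_samples < 1L)
    stop("configuration error: stride must be >= 1", call. = FALSE)
  structure(list(length_samples = as.integer(length_samples),
                 stride_samples = as.integer(stride_samples),
                 label_rule = label_rule),
            class = "window_spec")
}

#' STFT configuration
#'
#' 64-point Hann-windowed DFT with 32-point overlap.  At 1.5 kHz the
#' one-sided spectrum has 33 bins spanning 0-750 Hz; since most sEMG energy
#' sits below 200 Hz only the first `retain_rows = 9` rows (0-187.5 Hz) are
#' kept.
#'
#' @param n_fft DFT length (samples per frame).
#' @param hop Hop between frame starts in samples.
#' @param retain_rows Number of low-frequency rows kept.
#' @param magnitude_scale `"linear"` magnitude or `"log"` (`log1p` of it).
#' @return An `stft_config` list.
#' @export
stft_config <- function(n_fft = 64L, hop = 32L, retain_rows = 9L,
                        magnitude_scale = c("linear", "log")) {
  magnitude_scale <- match.arg(magnitude_scale)
  if (retain_rows > n_fft %/% 2L + 1L)
    stop("configuration error: retain_rows exceeds the one-sided bin count",
         call. = FALSE)
  structure(list(n_fft = as.integer(n_fft), hop = as.integer(hop),
                 retain_rows = as.integer(retain_rows),
                 magnitude_scale = magnitude_scale),
            class = "stft_config")
}

#' Waveform length
#'
#' Sum of absolute successive differences, `sum(|y[n] - y[n-1]|)` for
#' `n = 2..N`: the total path length of the waveform, reflecting signal
#' complexity.
#'
#' @param y Numeric vector, length >= 2.
#' @return Scalar.
#' @export
wave_length <- function(y) {
  if (length(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  sum(abs(diff(y)))
}

#' Mean absolute value
#' @param y Numeric vector.
#' @return `mean(abs(y))`, the average rectified amplitude.
#' @export
mean_absolute_value <- function(y) mean(abs(y))

#' Root mean square
#' @param y Numeric vector.
#' @return `sqrt(mean(y^2))`.
#' @export
root_mean_square <- function(y) sqrt(mean(y^2))

#' Signal variance (sample variance, N - 1 denominator)
#' @param y Numeric vector, length >= 2.
#' @return Scalar.
#' @export
signal_variance <- function(y) {
  if (length(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::var(y)
}

#' Thresholded zero-crossing count
#'
#' Number of sign changes whose amplitude step exceeds the threshold: counts
#' `n` in `2..N` with `y[n] * y[n-1] < 0` and `|y[n] - y[n-1]| >= eps`.
#'
#' @param y Numeric vector, length >= 2.
#' @param eps Nonnegative amplitude threshold suppressing noise-level
#'   crossings.
#' @return Integer count.
#' @export
zero_crossings <- function(y, eps = 0.01) {
  if (length(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (eps < 0) stop("eps must be nonnegative", call. = FALSE)
  a <- y[-length(y)]; b <- y[-1L]
  sum(a * b < 0 & abs(b - a) >= eps)
}

#' Row names of the time-domain feature matrix
#' @return `c("WL", "MAV", "VAR", "RMS", "ZC")`.
#' @export
td_feature_names <- function() c("WL", "MAV", "VAR", "RMS", "ZC")

#' Time-domain feature matrix of one window
#'
#' Applies the five classical features per channel, giving the 5 x 8 matrix
#' (rows WL, MAV, VAR, RMS, ZC; columns in [semg_channels()] order).
#'
#' @param raw window-length x 8 matrix of standardized sEMG.
#' @param eps Zero-crossing amplitude threshold (default 0.01, i.e. 1% of
#'   the unit post-standardization channel SD).
#' @return 5 x 8 numeric matrix.
#' @export
time_domain_matrix <- function(raw, eps = 0.01) {
  out <- rbind(
    WL  = apply(raw, 2L, wave_length),
    MAV = apply(raw, 2L, mean_absolute_value),
    VAR = apply(raw, 2L, signal_variance),
    RMS = apply(raw, 2L, root_mean_square),
    ZC  = apply(raw, 2L, zero_crossings, eps = eps))
  colnames(out) <- colnames(raw)
  out
}

# Hann window of length n (symmetric cosine taper)
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' STFT magnitude spectrogram of one window
#'
#' Per channel: Hann-windowed `n_fft`-point DFT magnitudes at hop `hop`.
#' A real 64-point frame has 33 one-sided bins with centers `k * fs / 64`
#' (0-750 Hz at 1.5 kHz); the first `retain_rows` rows (0-187.5 Hz for 9
#' rows) are retained and frames stacked along the time axis.
#'
#' @param raw window-length x channels matrix; the window length must be at
#'   least `n_fft` and satisfy `(length - n_fft) %% hop == 0` for an exact
#'   frame tiling (320 gives 9 frames).
#' @param cfg An [stft_config()].
#' @return Array `retain_rows x n_frames x channels`
#'   (frequency x time x channel); 9 x 9 x 8 under the defaults.
#' @export
stft_spectrogram <- function(raw, cfg = stft_config()) {
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 1L)
  n <- nrow(raw)
  if (n < cfg$n_fft)
    stop("segment shorter than the STFT frame length", call. = FALSE)
  n_frames <- (n - cfg$n_fft) %/% cfg$hop + 1L
  w <- hann_window(cfg$n_fft)
  nb <- cfg$n_fft %/% 2L + 1L
  out <- array(0, dim = c(cfg$retain_rows, n_frames, ncol(raw)))
  for (ch in seq_len(ncol(raw))) {
    for (f in seq_len(n_frames)) {
      i0 <- (f - 1L) * cfg$hop + 1L
      spec <- Mod(stats::fft(raw[i0:(i0 + cfg$n_fft - 1L), ch] * w))[seq_len(nb)]
      out[, f, ch] <- spec[seq_len(cfg$retain_rows)]
    }
  }
  if (cfg$magnitude_scale == "log") out <- log1p(out)
  out
}

#' One-sided STFT bin count and retained-row frequencies
#'
#' @param cfg An [stft_config()].
#' @param fs Sampling rate in Hz.
#' @return List with `n_bins` (one-sided bin count, `n_fft/2 + 1`) and
#'   `freqs` (center frequencies in Hz of the retained rows,
#'   `k * fs / n_fft` for `k = 0 .. retain_rows - 1`).
#' @export
stft_bins <- function(cfg = stft_config(), fs = 1500) {
  list(n_bins = cfg$n_fft %/% 2L + 1L,
       freqs = (seq_len(cfg$retain_rows) - 1L) * fs / cfg$n_fft)
}

#' Segment a recording into analysis windows
#'
#' Slides a window over a preprocessed, labelled recording.  Each window
#' carries its raw 8-channel slice, a gait label (majority or center rule)
#' and the regression target: the joint angles at the window's final sample,
#' i.e. the current state being predicted.
#'
#' @param rec A labelled `gait_recording` (sEMG already conditioned).
#' @param spec A [window_spec()].
#' @return List of windows, each a list with `raw`, `gait`, `angles`,
#'   `start`, `end`, `cycle`.
#' @export
segment_recording <- function(rec, spec = window_spec()) {
  validate_recording(rec)
  if (is.null(rec$labels))
    stop("recording must be labelled before segmentation", call. = FALSE)
  n <- nrow(rec$semg)
  L <- spec$length_samples
  if (n < L) stop("recording shorter than one window", call. = FALSE)
  starts <- seq.int(1L, n - L + 1L, by = spec$stride_samples)
  codes <- as.integer(rec$labels)
  cycles <- label_cycles(rec$labels)
  lapply(starts, function(i0) {
    i1 <- i0 + L - 1L
    win_codes <- codes[i0:i1]
    gait <- if (spec$label_rule == "center") {
      win_codes[(L + 1L) %/% 2L]
    } else {
      as.integer(names(which.max(table(win_codes))))
    }
    list(raw = rec$semg[i0:i1, , drop = FALSE], gait = gait,
         angles = rec$angles[i1, ], start = i0, end = i1,
         cycle = cycles[i1])
  })
}

#' Extract the full feature set of a recording
#'
#' Segments the recording and fills both feature representations of every
#' window, producing the arrays consumed by the multi-branch network.
#'
#' @param rec A labelled, preprocessed `gait_recording`.
#' @param spec A [window_spec()].
#' @param stft An [stft_config()].
#' @param zc_eps Zero-crossing threshold passed to [time_domain_matrix()].
#' @return An `emg_features` object: list with arrays `raw`
#'   (windows x length x 8), `td` (windows x 5 x 8), `spec`
#'   (windows x 9 x 9 x 8), integer `gait`, matrix `angles` (windows x 3),
#'   and a `manifest` data.frame (window start/end sample and cycle index).
#' @export
featurize_recording <- function(rec, spec = window_spec(),
                                stft = stft_config(), zc_eps = 0.01) {
  wins <- segment_recording(rec, spec)
  nw <- length(wins)
  L <- spec$length_samples
  n_frames <- (L - stft$n_fft) %/% stft$hop + 1L
  raw <- array(0, c(nw, L, 8L))
  td <- array(0, c(nw, 5L, 8L))
  sp <- array(0, c(nw, stft$retain_rows, n_frames, 8L))
  gait <- integer(nw)
  angles <- matrix(0, nw, 3L, dimnames = list(NULL, joint_names()))
  for (k in seq_len(nw)) {
    w <- wins[[k]]
    raw[k, , ] <- w$raw
    td[k, , ] <- time_domain_matrix(w$raw, eps = zc_eps)
    sp[k, , , ] <- stft_spectrogram(w$raw, stft)
    gait[k] <- w$gait
    angles[k, ] <- w$angles
  }
  structure(list(raw = raw, td = td, spec = sp, gait = gait, angles = angles,
                 manifest = data.frame(
                   start = vapply(wins, `[[`, integer(1), "start"),
                   end = vapply(wins, `[[`, integer(1), "end"),
                   cycle = vapply(wins, `[[`, integer(1), "cycle")),
                 sampling_rate = rec$sampling_rate),
            class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("<emg_features> %d windows (raw %d x 8, td 5 x 8, spec %s)\n",
              length(x$gait), dim(x$raw)[2],
              paste(dim(x$spec)[-1], collapse = " x ")))
  tab <- table(factor(x$gait, levels = 0:3, labels = gait_phase_names()))
  cat("  gait:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a feature store
#'
#' Features are stored as an RDS file plus a JSON manifest recording window
#' provenance (source sample indices and cycle ids) for reproducibility
#' audits.
#'
#' @param feats An `emg_features` object.
#' @param path Output `.rds` path; the manifest goes to `<path>.json`.
#' @return `path` invisibly (`write_features`); the `emg_features` object
#'   (`read_features`).
#' @export
write_features <- function(feats, path) {
  stopifnot(inherits(feats, "emg_features"))
  saveRDS(feats, path)
  jsonlite::write_json(
    list(n_windows = length(feats$gait),
         sampling_rate = feats$sampling_rate,
         manifest = feats$manifest),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature store not found: ", path, call. = FALSE)
  feats <- readRDS(path)
  stopifnot(inherits(feats, "emg_features"))
  feats
}
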