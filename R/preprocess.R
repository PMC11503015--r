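# Filtering, standardization and footswitch-to-gait-label conversion.

#' Butterworth filter specification
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Analog prototype order (the default second-order design is
#'   the standard choice for sEMG conditioning).
#' @param zero_phase Apply the filter forward and backward (zero phase lag,
#'   squared magnitude response); `FALSE` gives the causal single pass for
#'   streaming use.
#' @return A `filter_spec` list.
#' @examples
#' emg_bandpass <- filter_spec("bandpass", 20, 300)
#' mains_notch <- filter_spec("bandstop", 49, 51)
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"),
                        low_hz, high_hz, order = 2L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || low_hz >= high_hz)
    stop("configuration error: need 0 < low_hz < high_hz", call. = FALSE)
  if (order < 1L) stop("configuration error: order must be >= 1", call. = FALSE)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

design_butter <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop("configuration error: cutoff at or above the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) * 2 / fs,
                 type = if (spec$kind == "bandpass") "pass" else "stop")
}

#' Analytic Butterworth magnitude response
#'
#' Magnitude of the designed digital filter's transfer function evaluated at
#' frequency `f`, i.e. `|B(e^{-i w}) / A(e^{-i w})|` with `w = 2 pi f / fs`.
#' For `zero_phase = TRUE` the forward-backward response `|H|^2` is returned.
#'
#' @param spec A [filter_spec()].
#' @param f Frequencies in Hz (vectorized).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of magnitude gains.
#' @export
butterworth_response <- function(spec, f, fs) {
  bf <- design_butter(spec, fs)
  z <- exp(-1i * 2 * pi * f / fs)
  h <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(seq_along(bf$b) - 1L))
    den <- sum(bf$a * zz^(seq_along(bf$a) - 1L))
    Mod(num / den)
  }, numeric(1))
  if (spec$zero_phase) h^2 else h
}

# forward-backward filtering with reflective padding (3 x the filter's
# coefficient span) to suppress edge transients
filtfilt_reflect <- function(bf, x) {
  np <- 3L * (max(length(bf$b), length(bf$a)) - 1L)
  np <- min(np, length(x) - 1L)
  pad <- c(2 * x[1] - x[np:1 + 1L], x, 2 * x[length(x)] - x[length(x) - 1:np])
  y <- signal::filter(bf, pad)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(np + 1L):(np + length(x))]
}

#' Apply a Butterworth filter per channel
#'
#' Designs the digital Butterworth filter given by `spec` and applies it to
#' every column of `x`.  Zero-phase mode runs the filter forward and
#' backward (doubling the effective order and cancelling phase lag), using
#' reflective end padding; causal mode is a single forward pass.
#'
#' @param x Numeric vector or samples x channels matrix; must be finite.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return Filtered signal of the same shape as `x`.
#' @examples
#' fs <- 1500
#' x <- sin(2 * pi * 50 * (0:4499) / fs)
#' y <- butterworth_filter(x, filter_spec("bandstop", 49, 51), fs)
#' @export
butterworth_filter <- function(x, spec, fs) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  if (anyNA(xm) || any(!is.finite(xm)))
    stop("data error: signal contains non-finite values", call. = FALSE)
  bf <- design_butter(spec, fs)
  out <- xm
  for (j in seq_len(ncol(xm))) {
    out[, j] <- if (spec$zero_phase) filtfilt_reflect(bf, xm[, j])
                else as.numeric(signal::filter(bf, xm[, j]))
  }
  if (vec) out[, 1L] else out
}

#' Standard sEMG conditioning chain
#'
#' The default conditioning applied before feature extraction: 20-300 Hz
#' band-pass (the dominant sEMG energy band) followed by a 49-51 Hz band-stop
#' against mains interference, both second-order zero-phase Butterworth
#' designs, then per-channel zero standardization.
#'
#' @param semg samples x channels sEMG matrix.
#' @param fs Sampling rate in Hz.
#' @param bandpass,bandstop [filter_spec()]s; pass `NULL` to skip a stage.
#' @return Filtered, standardized matrix of the same shape.
#' @export
preprocess_semg <- function(semg, fs,
                            bandpass = filter_spec("bandpass", 20, 300),
                            bandstop = filter_spec("bandstop", 49, 51)) {
  out <- semg
  if (!is.null(bandpass)) out <- butterworth_filter(out, bandpass, fs)
  if (!is.null(bandstop)) out <- butterworth_filter(out, bandstop, fs)
  standardize(out)
}

#' Zero standardization
#'
#' Centers and scales every channel to mean 0 and unit standard deviation
#' (sample SD, `N - 1` denominator), statistics computed per channel over the
#' whole recording.
#'
#' @param x Numeric vector or samples x channels matrix.
#' @return Standardized signal of the same shape.
#' @export
standardize <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  sds <- apply(xm, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(xm)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("data error: zero-variance channel(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(xm, 2L, colMeans(xm)), 2L, sds, "/")
  if (vec) out[, 1L] else out
}

#' Smooth plantar-pressure channels
#'
#' Centered moving average per channel; edge windows shrink so the output
#' length equals the input length.
#'
#' @param pressure samples x channels matrix (or vector).
#' @param window_s Window length in seconds.
#' @param fs Sampling rate in Hz.
#' @return Smoothed signal of the same shape.
#' @export
smooth_pressure <- function(pressure, window_s = 0.02, fs = 1500) {
  vec <- is.null(dim(pressure))
  xm <- if (vec) matrix(pressure, ncol = 1L) else pressure
  window <- max(1L, round(window_s * fs))
  if (window >= nrow(xm))
    stop("smoothing window must be shorter than the signal", call. = FALSE)
  out <- apply(xm, 2L, moving_average, window = window)
  dimnames(out) <- dimnames(xm)
  if (vec) out[, 1L] else out
}

# contact-pattern -> phase rule on the right-foot switches:
#   no contact            -> SW
#   heel only             -> IC
#   heel + forefoot       -> MSt
#   forefoot/toe, no heel -> TSt
contact_to_phase <- function(heel, fore) {
  p <- gait_phases()
  out <- rep(p[["SW"]], length(heel))
  out[heel & !fore] <- p[["IC"]]
  out[heel & fore] <- p[["MSt"]]
  out[!heel & fore] <- p[["TSt"]]
  out
}

# merge label runs shorter than min_len into their predecessor
debounce_codes <- function(codes, min_len) {
  repeat {
    r <- rle(codes)
    short <- which(r$lengths < min_len)
    short <- short[short > 1L]
    if (length(short) == 0L) break
    b <- short[1L]
    r$values[b] <- r$values[b - 1L]
    codes <- inverse.rle(r)
  }
  codes
}

#' Convert plantar pressure into the four-phase gait label stream
#'
#' Thresholds each right-foot switch at `threshold` times its 95th
#' percentile, maps the contact pattern to a phase (no contact = SW, heel
#' only = IC, heel plus forefoot = MSt, forefoot/toe without heel = TSt) and
#' debounces the stream with a minimum phase duration.
#'
#' @param pressure samples x 8 matrix of (smoothed) switch channels, right
#'   foot in columns 1-4 (heel, fifth metatarsal, first metatarsal, big toe).
#' @param threshold Contact threshold as a fraction of each channel's 95th
#'   percentile, in (0, 1).
#' @param fs Sampling rate in Hz.
#' @param min_phase_s Minimum phase duration in seconds used for debouncing.
#' @return A `gait_labels` series covering every sample.
#' @export
extract_gait_phases <- function(pressure, threshold = 0.5, fs = 1500,
                                min_phase_s = 0.05) {
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0, 1)", call. = FALSE)
  if (all(abs(pressure) < .Machine$double.eps))
    stop("data error: all-zero pressure, no gait detectable", call. = FALSE)
  right <- pressure[, 1:4, drop = FALSE]
  p95 <- apply(right, 2L, stats::quantile, probs = 0.95, names = FALSE)
  # per-channel threshold, floored at a quarter of the strongest channel so
  # a switch that never fires is not mistaken for permanent contact
  thr <- pmax(threshold * p95, 0.25 * max(p95))
  on <- sweep(right, 2L, thr, ">")
  heel <- on[, 1L]
  fore <- on[, 2L] | on[, 3L] | on[, 4L]
  codes <- contact_to_phase(heel, fore)
  codes <- debounce_codes(codes, max(1L, round(min_phase_s * fs)))
  new_gait_labels(codes, fs)
}

#' Cycle index per sample from a label stream
#'
#' Numbers the gait cycles by counting swing onsets; samples before the first
#' onset belong to cycle 1.  Used for leakage-free cycle-grouped data splits.
#'
#' @param labels A `gait_labels` series.
#' @return Integer vector of 1-based cycle indices, one per sample.
#' @export
label_cycles <- function(labels) {
  id <- attr(labels, "cycle_id")
  if (!is.null(id)) return(id)
  codes <- as.integer(labels)
  sw <- gait_phases()[["SW"]]
  onset <- codes == sw & c(TRUE, codes[-length(codes)] != sw)
  onset[1L] <- TRUE
  cumsum(onset)
}
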