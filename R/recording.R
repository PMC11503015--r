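#' Synchronized multi-channel gait recording
#'
#' A `gait_recording` holds one walking session: 8 sEMG channels, 8 plantar
#' pressure switch channels, 3 joint angles and (optionally) a per-sample
#' gait-phase label stream, all sampled at a common rate.
#'
#' @param semg samples x 8 numeric matrix (mV-scale units).
#' @param pressure samples x 8 numeric matrix of switch traces.
#' @param angles samples x 3 numeric matrix (degrees: hip, knee, ankle).
#' @param labels optional `gait_labels` series of the same length.
#' @param sampling_rate sampling frequency in Hz.
#' @param seed optional integer provenance seed.
#' @return A `gait_recording` object.
#' @name gait_recording
NULL

new_gait_recording <- function(semg, pressure, angles, labels = NULL,
                               sampling_rate, seed = NA_integer_) {
  structure(list(semg = semg, pressure = pressure, angles = angles,
                 labels = labels, sampling_rate = sampling_rate,
                 seed = seed),
            class = "gait_recording")
}

#' Validate a gait recording
#'
#' Checks that every channel block shares the sample count, that no block
#' contains missing values and that label codes come from the four-phase
#' enumeration.
#'
#' @param rec A `gait_recording`.
#' @return `rec`, invisibly; otherwise an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  n <- nrow(rec$semg)
  if (ncol(rec$semg) != 8L) stop("semg must have 8 channels", call. = FALSE)
  if (ncol(rec$pressure) != 8L) stop("pressure must have 8 channels", call. = FALSE)
  if (ncol(rec$angles) != 3L) stop("angles must have 3 channels", call. = FALSE)
  if (nrow(rec$pressure) != n || nrow(rec$angles) != n)
    stop("all channel blocks must share the sample count", call. = FALSE)
  if (anyNA(rec$semg) || anyNA(rec$pressure) || anyNA(rec$angles))
    stop("recording contains missing samples", call. = FALSE)
  if (!is.null(rec$labels)) {
    if (length(rec$labels) != n)
      stop("labels must cover every sample", call. = FALSE)
    if (!all(as.integer(rec$labels) %in% gait_phases()))
      stop("labels contain codes outside the four-phase enumeration",
           call. = FALSE)
  }
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  invisible(rec)
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d samples (%.1f s at %g Hz)\n",
              nrow(x$semg), nrow(x$semg) / x$sampling_rate, x$sampling_rate))
  cat(sprintf("  semg: 8 ch (%s)\n", paste(semg_channels(), collapse = " ")))
  cat("  pressure: 8 footswitch channels; angles: hip/knee/ankle (deg)\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(as.integer(x$labels), levels = 0:3,
                        labels = gait_phase_names()))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  } else cat("  labels: none\n")
  invisible(x)
}

#' Write a gait recording to disk
#'
#' Stores the session as one wide CSV (all channels plus the label code, one
#' row per sample) and a JSON sidecar holding the sampling rate, channel
#' names and provenance seed.
#'
#' @param rec A `gait_recording`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- data.table::data.table(
    rec$semg, rec$pressure, rec$angles,
    label = if (is.null(rec$labels)) NA_integer_ else as.integer(rec$labels))
  data.table::setnames(df, c(paste0("semg_", semg_channels()),
                             paste0("pressure_", pressure_channels()),
                             paste0("angle_", joint_names()), "label"))
  data.table::fwrite(df, path)
  meta <- list(sampling_rate = rec$sampling_rate, seed = rec$seed,
               semg_channels = semg_channels(),
               pressure_channels = pressure_channels(),
               joints = joint_names(),
               has_labels = !is.null(rec$labels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a gait recording written by [write_recording()]
#'
#' @param path CSV path previously written by [write_recording()].
#' @return A `gait_recording`.
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("recording files not found: ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- data.table::fread(path)
  semg <- as.matrix(df[, paste0("semg_", semg_channels()), with = FALSE])
  colnames(semg) <- semg_channels()
  pressure <- as.matrix(df[, paste0("pressure_", pressure_channels()),
                           with = FALSE])
  colnames(pressure) <- pressure_channels()
  angles <- as.matrix(df[, paste0("angle_", joint_names()), with = FALSE])
  colnames(angles) <- joint_names()
  labels <- NULL
  if (isTRUE(meta$has_labels))
    labels <- new_gait_labels(df$label, meta$sampling_rate)
  rec <- new_gait_recording(semg, pressure, angles, labels,
                            meta$sampling_rate,
                            seed = if (is.null(meta$seed)) NA_integer_
                                   else meta$seed)
  validate_recording(rec)
  rec
}
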