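# Declarative pipeline configuration: one nested key-value structure with
# every stage's parameters, all defaults embedded, unknown keys rejected.

#' Default pipeline configuration
#'
#' Nested sections mirror the pipeline stages (`simulate`, `preprocess`,
#' `features`, `model`, `train`) plus a global `seed`.  Every runner accepts
#' this structure, so the end-to-end pipeline works with zero arguments.
#'
#' @return A `pipeline_config` (nested named list).
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(
      sampling_rate = 1500, n_cycles = 200L, cycle_duration = 1.0,
      phase_fractions = c(0.4, 0.2, 0.2, 0.2),
      emg_band = c(20, 150), mains_amplitude = 0.1,
      angle_amplitude = 1, measurement_noise_sd = 0.05,
      pressure_noise_sd = 0.05, edge_jitter_s = 0.005,
      cycle_jitter = 0.05),
    preprocess = list(
      bandpass = c(20, 300), bandstop = c(49, 51), order = 2L,
      zero_phase = TRUE, pressure_window_s = 0.02,
      threshold = 0.5, min_phase_s = 0.05),
    features = list(
      window = 320L, stride = 160L, label_rule = "majority",
      zc_eps = 0.01, n_fft = 64L, hop = 32L, retain_rows = 9L,
      magnitude_scale = "linear"),
    model = list(
      conv1_filters = 16L, conv2_filters = 32L, conv2d_filters = 16L,
      gru_hidden = 32L, fc_hidden = 128L, lambda = 0.1),
    train = list(
      epochs = 15L, batch_size = 64L, lr = 1e-3, val_fraction = 0.1,
      train_fraction = 0.8, group_by_cycle = TRUE)),
    class = "pipeline_config")
}

# recursive merge of user values into the defaults; unknown keys are errors
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' Reads a YAML file, overlays it on [default_pipeline_config()] and rejects
#' unknown keys.  `path = NULL` returns the defaults.
#'
#' @param path YAML file path or `NULL`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "pipeline_config")
  }
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_pipeline_config()].
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# materialize stage objects from the config
config_sim <- function(config) {
  s <- config$simulate
  sim_config(sampling_rate = s$sampling_rate, n_cycles = s$n_cycles,
             cycle_duration = s$cycle_duration,
             phase_fractions = s$phase_fractions,
             emg_band = s$emg_band, mains_amplitude = s$mains_amplitude,
             angle_amplitude = s$angle_amplitude,
             measurement_noise_sd = s$measurement_noise_sd,
             pressure_noise_sd = s$pressure_noise_sd,
             edge_jitter_s = s$edge_jitter_s, cycle_jitter = s$cycle_jitter,
             seed = config$seed)
}

config_window <- function(config) {
  f <- config$features
  window_spec(f$window, f$stride, f$label_rule)
}

config_stft <- function(config) {
  f <- config$features
  stft_config(f$n_fft, f$hop, f$retain_rows, f$magnitude_scale)
}

config_model <- function(config) {
  m <- config$model
  f <- config$features
  n_frames <- (f$window - f$n_fft) %/% f$hop + 1L
  model_config(conv1_filters = m$conv1_filters,
               conv2_filters = m$conv2_filters,
               conv2d_filters = m$conv2d_filters,
               gru_hidden = m$gru_hidden, fc_hidden = m$fc_hidden,
               lambda = m$lambda, input_length = f$window,
               spec_dim = c(f$retain_rows, n_frames, 8L))
}

# run manifest: everything needed to reproduce an artifact
write_manifest <- function(config, dir, stage, extra = list()) {
  manifest <- c(list(stage = stage, seed = config$seed,
                     config_hash = config_hash(unclass(config)),
                     package_version = as.character(
                       utils::packageVersion("emgait")),
                     config = unclass(config),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE)
  invisible(manifest)
}
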