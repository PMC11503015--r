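# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small default-noise session plus its preprocessed/featurized forms
small_session <- function() cached("small_session", {
  generate_session(sim_config(n_cycles = 6, seed = 42))
})

small_features <- function() cached("small_features", {
  rec <- small_session()
  semg <- preprocess_semg(rec$semg, rec$sampling_rate)
  rec2 <- emgait:::new_gait_recording(semg, rec$pressure, rec$angles,
                                      rec$labels, rec$sampling_rate)
  featurize_recording(rec2)
})

# deliberately small network for training smoke tests
tiny_model_config <- function() {
  model_config(conv1_filters = 4L, conv2_filters = 8L, conv2d_filters = 4L,
               gru_hidden = 8L, fc_hidden = 16L)
}

tiny_pipeline_config <- function(seed = 5L) {
  cfg <- default_pipeline_config()
  cfg$seed <- seed
  cfg$simulate$n_cycles <- 8L
  cfg$model <- list(conv1_filters = 4L, conv2_filters = 8L,
                    conv2d_filters = 4L, gru_hidden = 8L, fc_hidden = 16L,
                    lambda = 0.1)
  cfg$train$epochs <- 2L
  cfg
}

# brute-force loop oracles for the five time-domain features
oracle_wl <- function(y) {
  s <- 0
  for (n in 2:length(y)) s <- s + abs(y[n] - y[n - 1])
  s
}
oracle_mav <- function(y) {
  s <- 0
  for (n in seq_along(y)) s <- s + abs(y[n])
  s / length(y)
}
oracle_var <- function(y) {
  m <- 0
  for (n in seq_along(y)) m <- m + y[n]
  m <- m / length(y)
  s <- 0
  for (n in seq_along(y)) s <- s + (y[n] - m)^2
  s / (length(y) - 1)
}
oracle_rms <- function(y) {
  s <- 0
  for (n in seq_along(y)) s <- s + y[n]^2
  sqrt(s / length(y))
}
oracle_zc <- function(y, eps) {
  k <- 0L
  for (n in 2:length(y))
    if (y[n] * y[n - 1] < 0 && abs(y[n] - y[n - 1]) >= eps) k <- k + 1L
  k
}

# brute-force confusion-matrix metrics (independent of the implementation)
oracle_cls_metrics <- function(cm) {
  K <- nrow(cm)
  prec <- sens <- numeric(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    prec[c] <- if (sum(cm[, c]) > 0) tp / sum(cm[, c]) else 0
    sens[c] <- if (sum(cm[c, ]) > 0) tp / sum(cm[c, ]) else 0
  }
  list(accuracy = 100 * sum(diag(cm)) / sum(cm),
       pmap = 100 * mean(prec), pmas = 100 * mean(sens),
       pmip = 100 * sum(diag(cm)) / sum(cm),
       pmis = 100 * sum(diag(cm)) / sum(cm),
       prec = 100 * prec, sens = 100 * sens)
}

# steady-state amplitude of a sinusoid at frequency f in signal y (regression
# on sin/cos over the central portion, transients excluded)
tone_amplitude <- function(y, f, fs) {
  n <- length(y)
  idx <- floor(n * 0.3):floor(n * 0.7)
  tt <- (idx - 1) / fs
  fit <- stats::lm(y[idx] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
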