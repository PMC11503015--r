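# Training loop (Adam), leakage-aware 80/20 splitting and the evaluation
# metric suite: confusion-derived classification metrics with macro/micro
# averaging plus per-joint RMSE, zero-lag cross-correlation and relative
# error.

# ---- nested parameter-tree helpers ----------------------------------------

# walk two parameter trees in parallel, pairing children by name where
# names exist (gradient lists are not built in parameter order)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a))) names(a) else seq_along(a)
    out <- lapply(keys, function(k) tree_map2(f, a[[k]], b[[k]]))
    names(out) <- names(a)
    return(out)
  }
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

# ---- dataset handling -----------------------------------------------------

#' Subset a feature set by window index
#' @param feats An `emg_features` object.
#' @param idx Integer window indices.
#' @return The subsetted `emg_features`.
#' @export
subset_features <- function(feats, idx) {
  structure(list(raw = feats$raw[idx, , , drop = FALSE],
                 td = feats$td[idx, , , drop = FALSE],
                 spec = feats$spec[idx, , , , drop = FALSE],
                 gait = feats$gait[idx],
                 angles = feats$angles[idx, , drop = FALSE],
                 manifest = feats$manifest[idx, , drop = FALSE],
                 sampling_rate = feats$sampling_rate),
            class = "emg_features")
}

#' Train/test split of a window set
#'
#' Disjoint, exhaustive 80/20 split.  With `group_by_cycle` (the default)
#' whole gait cycles go to one side, so overlapping windows from the same
#' cycle can never straddle the split and leak information.  Without
#' grouping, an optionally gait-stratified random window split is used.
#'
#' @param feats An `emg_features` object.
#' @param train_fraction Fraction of windows on the training side, in (0,1).
#' @param group_by_cycle Keep whole cycles together (recommended for
#'   overlapping windows).
#' @param stratify_by_gait For ungrouped splits, preserve class proportions.
#' @param seed Integer seed.
#' @return List with `train` and `test` (`emg_features`) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_windows <- function(feats, train_fraction = 0.8,
                          group_by_cycle = TRUE, stratify_by_gait = FALSE,
                          seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(feats$gait)
  if (group_by_cycle) {
    cyc <- feats$manifest$cycle
    u <- sample(unique(cyc))
    counts <- table(cyc)[as.character(u)]
    take <- cumsum(as.numeric(counts)) <= round(train_fraction * n)
    if (!any(take)) take[1L] <- TRUE
    train_idx <- which(cyc %in% u[take])
  } else if (stratify_by_gait) {
    train_idx <- unlist(lapply(split(seq_len(n), feats$gait), function(ix)
      sample(ix, round(train_fraction * length(ix)))), use.names = FALSE)
  } else {
    train_idx <- sample(n, round(train_fraction * n))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_features(feats, train_idx),
       test = subset_features(feats, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# ---- training -------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

batch_of <- function(feats, idx) {
  list(raw = feats$raw[idx, , , drop = FALSE],
       td = feats$td[idx, , , drop = FALSE],
       spec = feats$spec[idx, , , , drop = FALSE],
       gait = feats$gait[idx],
       angles = feats$angles[idx, , drop = FALSE])
}

#' Train the multi-branch model
#'
#' Minimizes `CE(gait) + lambda * MSE(angles)` with Adam.  A fixed 10%
#' validation carve-out of the training windows is evaluated every epoch
#' (total loss and gait accuracy curves); the parameters with the best
#' validation loss are retained.  Feature normalization statistics (mean/SD
#' of every time-domain and spectrogram entry) are fitted on the training
#' side and stored inside the model.
#'
#' @param model An `emg_model` (fresh from [emg_model()] or a checkpoint).
#' @param train_set `emg_features` to train on.
#' @param epochs Training epochs (about 40 suffices on the synthetic data).
#' @param batch_size Windows per gradient step.
#' @param lr Initial Adam learning rate; a step schedule halves it at 60%
#'   and again at 85% of the epoch budget (disable with `lr_decay = FALSE`).
#' @param lr_decay Apply the step schedule.
#' @param val_fraction Fraction of training windows carved out for the
#'   per-epoch validation curve.
#' @param seed Integer seed (shuffling and carve-out).
#' @param verbose Print one line per epoch.
#' @return The trained `emg_model`, with a `history` data.frame attached
#'   (epoch, train_loss, val_loss, val_accuracy).
#' @export
train_model <- function(model, train_set, epochs = 40L, batch_size = 64L,
                        lr = 1e-3, lr_decay = TRUE, val_fraction = 0.1,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "emg_model"))
  set.seed(as.integer(seed))
  n <- length(train_set$gait)
  val_n <- max(1L, round(val_fraction * n))
  val_idx <- sort(sample(n, val_n))
  fit_idx <- setdiff(seq_len(n), val_idx)
  model$norm <- fit_normalization(subset_features(train_set, fit_idx))
  val_feats <- subset_features(train_set, val_idx)
  val_true <- val_feats$gait

  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, params = model$params, norm = model$norm)

  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_decay)
      lr * 0.5^(sum(ep > ceiling(epochs * c(0.6, 0.85)))) else lr
    ord <- sample(fit_idx)
    ep_loss <- 0; nb <- 0L
    for (i0 in seq.int(1L, length(ord), by = batch_size)) {
      idx <- ord[i0:min(i0 + batch_size - 1L, length(ord))]
      lg <- loss_and_grads(model, batch_of(train_set, idx))
      st <- adam_step(model$params, lg$grads, state, lr = lr_ep)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    val <- validation_pass(model, val_feats)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val$loss,
                                   val_accuracy = val$accuracy))
    if (val$loss < best$loss)
      best <- list(loss = val$loss, params = model$params, norm = model$norm)
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  val acc %.3f",
                      ep, ep_loss / nb, val$loss, val$accuracy))
  }
  model$params <- best$params
  model$history <- hist
  model
}

validation_pass <- function(model, feats, batch_size = 256L) {
  n <- length(feats$gait)
  loss <- 0; correct <- 0L
  for (i0 in seq.int(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    b <- batch_of(feats, idx)
    fwd <- forward_model(model, b)
    ce <- cross_entropy(fwd$gait_logits, b$gait)
    ms <- mse_loss(fwd$angles, b$angles)
    loss <- loss + (ce$loss + model$config$lambda * ms$loss) * length(idx)
    correct <- correct + sum(max.col(fwd$gait_probs) - 1L == b$gait)
  }
  list(loss = loss / n, accuracy = correct / n)
}

# ---- classification metrics -----------------------------------------------

#' Confusion matrix of gait predictions
#'
#' @param true,pred Integer phase codes 0..3.
#' @return 4 x 4 integer matrix, rows = true class, columns = predicted,
#'   labelled by [gait_phase_names()].
#' @export
confusion_matrix <- function(true, pred) {
  lev <- 0:3
  tab <- table(factor(true, levels = lev), factor(pred, levels = lev))
  m <- matrix(as.integer(tab), 4L, 4L,
              dimnames = list(true = gait_phase_names(),
                              pred = gait_phase_names()))
  m
}

#' Confusion-derived classification metrics
#'
#' Per-class precision `TP/(TP+FP)` and sensitivity `TP/(TP+FN)`, overall
#' accuracy, and their macro (unweighted class mean) and micro (pooled
#' counts) averages: PMAP/PMIP for precision, PMAS/PMIS for sensitivity.
#' All values in percent.  A class with zero predicted (or true) positives
#' has undefined precision (sensitivity); it is reported as 0 with a
#' warning.
#'
#' @param confusion 4 x 4 (or K x K) count matrix, rows = true, columns =
#'   predicted.
#' @return List with `per_class_precision`, `per_class_sensitivity`,
#'   `accuracy`, `pmap`, `pmip`, `pmas`, `pmis` (percent).
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  pred_pos <- colSums(confusion)
  true_pos <- rowSums(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)

  prec <- tp / pred_pos
  if (any(pred_pos == 0)) {
    warning("class(es) with zero predicted positives: precision reported as 0")
    prec[pred_pos == 0] <- 0
  }
  sens <- tp / true_pos
  if (any(true_pos == 0)) {
    warning("class(es) with zero true positives: sensitivity reported as 0")
    sens[true_pos == 0] <- 0
  }
  list(per_class_precision = 100 * prec,
       per_class_sensitivity = 100 * sens,
       accuracy = 100 * sum(tp) / total,
       pmap = 100 * mean(prec),
       pmip = 100 * sum(tp) / sum(pred_pos),
       pmas = 100 * mean(sens),
       pmis = 100 * sum(tp) / sum(true_pos))
}

# ---- regression metrics ---------------------------------------------------

#' Joint-angle regression metrics
#'
#' Per joint: RMSE in degrees, zero-lag cross-correlation (Pearson
#' correlation between the predicted and true angle series) and relative
#' error, defined as RMSE over the observed true range of motion, in
#' percent.
#'
#' @param pred,true N x 3 matrices of angles in degrees.
#' @return List with `rmse`, `xcorr`, `relative_error` (each length 3,
#'   named hip/knee/ankle).
#' @export
regression_metrics <- function(pred, true) {
  stopifnot(ncol(pred) == ncol(true), nrow(pred) == nrow(true))
  rmse <- sqrt(colMeans((pred - true)^2))
  xcorr <- vapply(seq_len(ncol(pred)), function(j)
    stats::cor(pred[, j], true[, j]), numeric(1))
  rng <- apply(true, 2L, function(x) diff(range(x)))
  rel <- 100 * rmse / rng
  nm <- colnames(true)
  if (is.null(nm)) nm <- joint_names()[seq_len(ncol(true))]
  names(rmse) <- names(xcorr) <- names(rel) <- nm
  list(rmse = rmse, xcorr = xcorr, relative_error = rel)
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate a trained model on a test window set
#'
#' Runs prediction, builds the confusion matrix and composes the full metric
#' suite; the per-window predicted vs true gait sequence and angle traces
#' are returned for plotting.
#'
#' @param model A trained `emg_model`.
#' @param test_set An `emg_features` object.
#' @return An `eval_report`: confusion matrix, classification metrics,
#'   regression metrics and the prediction traces.
#' @export
evaluate_model <- function(model, test_set) {
  pred <- predict_model(model, test_set)
  confusion <- confusion_matrix(test_set$gait, pred$gait_pred)
  cls <- classification_metrics(confusion)
  reg <- regression_metrics(pred$angles, test_set$angles)
  structure(list(confusion = confusion, classification = cls,
                 regression = reg,
                 traces = list(gait_true = test_set$gait,
                               gait_pred = pred$gait_pred,
                               angles_true = test_set$angles,
                               angles_pred = pred$angles,
                               window_end = test_set$manifest$end),
                 n_test = length(test_set$gait)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d test windows\n", x$n_test))
  cat(sprintf("  gait accuracy %.2f%% | PMAP %.2f PMIP %.2f PMAS %.2f PMIS %.2f\n",
              x$classification$accuracy, x$classification$pmap,
              x$classification$pmip, x$classification$pmas,
              x$classification$pmis))
  cat("  per-class precision (%):",
      paste(sprintf("%s=%.1f", gait_phase_names(),
                    x$classification$per_class_precision), collapse = " "),
      "\n")
  r <- x$regression
  for (j in names(r$rmse))
    cat(sprintf("  %-5s RMSE %.2f deg, xcorr %.3f, rel err %.1f%%\n",
                j, r$rmse[j], r$xcorr[j], r$relative_error[j]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(n_test = report$n_test,
              confusion = unclass(report$confusion),
              classification = report$classification,
              regression = report$regression)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
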