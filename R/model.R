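# The multi-branch network: branch 1 learns the raw 320 x 8 sEMG window
# through two conv1d(+ReLU+maxpool) stages feeding a 3-layer GRU; branch 2
# learns the 9 x 9 x 8 STFT spectrogram through a stride-2 conv2d(+ReLU+
# 2x2 maxpool); branch 3 runs a 3-layer GRU over the 5 x 8 time-domain
# feature matrix (features as time steps, channels as dimensions).  The
# three embeddings are concatenated and fed to two separate fully connected
# heads: a 4-way softmax gait classifier and a 3-output linear angle
# regressor.  Trained jointly with loss = CE + lambda * MSE.

#' Network hyper-parameters
#'
#' Kernel sizes, strides and layer counts are fixed by the architecture
#' (width-3 stride-1 valid conv1d, 3x3 stride-2 valid conv2d, three GRU
#' layers); the widths here are free choices sized to train on a single CPU
#' in minutes.
#'
#' @param conv1_filters,conv2_filters Kernel counts of the two 1-D conv
#'   layers of branch 1.
#' @param conv2d_filters Kernel count of the 2-D conv layer of branch 2.
#' @param gru_hidden Hidden size of every GRU layer (both stacks).
#' @param fc_hidden Width of the hidden fully connected layer in each head.
#' @param lambda Weight of the angle MSE term in the joint loss; the default
#'   0.1 balances a cross-entropy of order 1 against squared-degree errors
#'   of order 10^2.
#' @param input_length,n_channels Raw window geometry.
#' @param td_dim Time-domain matrix geometry (steps, dims).
#' @param spec_dim Spectrogram geometry (freq, time, channels).
#' @return A `model_config` list.
#' @export
model_config <- function(conv1_filters = 16L, conv2_filters = 32L,
                         conv2d_filters = 16L, gru_hidden = 32L,
                         fc_hidden = 128L, lambda = 0.1,
                         input_length = 320L, n_channels = 8L,
                         td_dim = c(5L, 8L), spec_dim = c(9L, 9L, 8L)) {
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 conv2d_filters = as.integer(conv2d_filters),
                 gru_hidden = as.integer(gru_hidden),
                 fc_hidden = as.integer(fc_hidden), lambda = lambda,
                 input_length = as.integer(input_length),
                 n_channels = as.integer(n_channels),
                 td_dim = as.integer(td_dim),
                 spec_dim = as.integer(spec_dim)),
            class = "model_config")
}

# declared layer-by-layer shape plan of branch 1 (lengths after each stage)
branch1_plan <- function(cfg) {
  t1 <- cfg$input_length - 2L          # conv1, valid width 3
  p1 <- t1 %/% 2L                      # pool 2
  t2 <- p1 - 2L                        # conv2
  p2 <- t2 %/% 2L                      # pool 2
  if (p2 < 1L)
    stop("input too short to survive two conv+pool stages", call. = FALSE)
  c(conv1 = t1, pool1 = p1, conv2 = t2, pool2 = p2)
}

#' Build the multi-branch model
#'
#' Initializes all trainable tensors (uniform in `+/- 1/sqrt(fan_in)`) under
#' the given seed and audits the declared layer shapes against an executed
#' forward pass on a dummy batch.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `emg_model` object (config, parameter list, optional feature
#'   normalization statistics).
#' @examples
#' m <- emg_model(seed = 1)
#' m
#' @export
emg_model <- function(config = model_config(), seed = 1L) {
  set.seed(as.integer(seed))
  rng <- function(n, s) stats::runif(n, -s, s)
  cfg <- config
  H <- cfg$gru_hidden
  plan <- branch1_plan(cfg)

  mk_fc <- function(d_in, d_out) {
    s <- 1 / sqrt(d_in)
    list(W = matrix(rng(d_in * d_out, s), d_in, d_out), b = rng(d_out, s))
  }
  mk_conv <- function(fan_in, d_out) {
    s <- 1 / sqrt(fan_in)
    list(W = matrix(rng(fan_in * d_out, s), fan_in, d_out), b = rng(d_out, s))
  }

  spat <- conv2d_out_dim(cfg$spec_dim[1])      # 4 for a 9 x 9 input
  flat2 <- (spat %/% 2L)^2L * cfg$conv2d_filters
  fusion <- as.integer(H + flat2 + H)

  params <- list(
    conv1 = mk_conv(3L * cfg$n_channels, cfg$conv1_filters),
    conv2 = mk_conv(3L * cfg$conv1_filters, cfg$conv2_filters),
    gru1 = list(gru_init(cfg$conv2_filters, H, rng),
                gru_init(H, H, rng), gru_init(H, H, rng)),
    conv2d = mk_conv(9L * cfg$spec_dim[3], cfg$conv2d_filters),
    gru3 = list(gru_init(cfg$td_dim[2], H, rng),
                gru_init(H, H, rng), gru_init(H, H, rng)),
    fc_gait1 = mk_fc(fusion, cfg$fc_hidden),
    fc_gait2 = mk_fc(cfg$fc_hidden, 4L),
    fc_ang1 = mk_fc(fusion, cfg$fc_hidden),
    fc_ang2 = mk_fc(cfg$fc_hidden, 3L))

  model <- structure(list(config = cfg, params = params, norm = NULL,
                          plan = plan, fusion_dim = fusion, seed = seed),
                     class = "emg_model")
  audit_shapes(model)
  model
}

#' @export
print.emg_model <- function(x, ...) {
  cfg <- x$config
  cat("<emg_model> three-branch CNN-GRU, multi-task (4-class gait + 3 angles)\n")
  cat(sprintf("  branch1: conv1d %d -> pool -> conv1d %d -> pool -> GRU x3 (H=%d)\n",
              cfg$conv1_filters, cfg$conv2_filters, cfg$gru_hidden))
  cat(sprintf("  branch2: conv2d %d (3x3, stride 2) -> ReLU -> 2x2 pool -> flatten\n",
              cfg$conv2d_filters))
  cat(sprintf("  branch3: GRU x3 (H=%d) over 5 steps of 8 dims\n", cfg$gru_hidden))
  cat(sprintf("  fusion %d -> FC %d -> {softmax(4), linear(3)}; lambda = %g\n",
              x$fusion_dim, cfg$fc_hidden, cfg$lambda))
  cat(sprintf("  %d trainable parameters\n", n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `emg_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity,
             numeric(1)))
}

# apply (or fit, if stats absent) the feature normalization used by the
# td and spectrogram branches; raw windows are already standardized upstream
normalize_batch <- function(model, batch) {
  nm <- model$norm
  if (is.null(nm)) return(batch)
  batch$td <- sweep(sweep(batch$td, c(2, 3), nm$td_mean), c(2, 3),
                    nm$td_sd, "/")
  batch$spec <- sweep(sweep(batch$spec, c(2, 3, 4), nm$spec_mean),
                      c(2, 3, 4), nm$spec_sd, "/")
  batch
}

fit_normalization <- function(feats) {
  list(td_mean = apply(feats$td, c(2, 3), mean),
       td_sd = apply(feats$td, c(2, 3), stats::sd) + 1e-8,
       spec_mean = apply(feats$spec, c(2, 3, 4), mean),
       spec_sd = apply(feats$spec, c(2, 3, 4), stats::sd) + 1e-8)
}

#' Forward pass of the multi-branch network
#'
#' @param model An `emg_model`.
#' @param batch List with arrays `raw` (B x 320 x 8), `td` (B x 5 x 8) and
#'   `spec` (B x 9 x 9 x 8); feature normalization stored in the model is
#'   applied here.
#' @param keep_cache Retain intermediate activations for a backward pass.
#' @return List with `gait_logits`, `gait_probs` (rows sum to 1), `angles`
#'   (degrees) and, if requested, `cache`.
#' @export
forward_model <- function(model, batch, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  if (!identical(dim(batch$raw)[-1], c(cfg$input_length, cfg$n_channels)))
    stop("raw window geometry does not match the model configuration",
         call. = FALSE)
  if (!identical(dim(batch$td)[-1], cfg$td_dim))
    stop("time-domain matrix must be ", cfg$td_dim[1], " steps x ",
         cfg$td_dim[2], " dims", call. = FALSE)
  if (!identical(dim(batch$spec)[-1], cfg$spec_dim))
    stop("spectrogram geometry does not match the model configuration",
         call. = FALSE)
  batch <- normalize_batch(model, batch)
  B <- dim(batch$raw)[1]

  c1 <- conv1d_forward(batch$raw, p$conv1$W, p$conv1$b)
  r1 <- relu_forward(c1$out)
  q1 <- pool1d_forward(r1$out)
  c2 <- conv1d_forward(q1$out, p$conv2$W, p$conv2$b)
  r2 <- relu_forward(c2$out)
  q2 <- pool1d_forward(r2$out)
  g1 <- gru_stack_forward(q2$out, p$gru1)
  T1 <- dim(g1$out)[2]
  e1 <- matrix(g1$out[, T1, ], B, model$config$gru_hidden)

  c3 <- conv2d_forward(batch$spec, p$conv2d$W, p$conv2d$b)
  r3 <- relu_forward(c3$out)
  q3 <- pool2d_forward(r3$out)
  e2 <- q3$out
  dim(e2) <- c(B, length(e2) / B)

  g3 <- gru_stack_forward(batch$td, p$gru3)
  T3 <- dim(g3$out)[2]
  e3 <- matrix(g3$out[, T3, ], B, model$config$gru_hidden)

  fused <- cbind(e1, e2, e3)
  hg <- fc_forward(fused, p$fc_gait1$W, p$fc_gait1$b)
  hg_r <- relu_forward(hg$out)
  logits <- fc_forward(hg_r$out, p$fc_gait2$W, p$fc_gait2$b)
  ha <- fc_forward(fused, p$fc_ang1$W, p$fc_ang1$b)
  ha_r <- relu_forward(ha$out)
  ang <- fc_forward(ha_r$out, p$fc_ang2$W, p$fc_ang2$b)

  out <- list(gait_logits = logits$out, gait_probs = softmax(logits$out),
              angles = ang$out)
  if (keep_cache)
    out$cache <- list(c1 = c1, r1 = r1, q1 = q1, c2 = c2, r2 = r2, q2 = q2,
                      g1 = g1, c3 = c3, r3 = r3, q3 = q3, g3 = g3,
                      hg = hg, hg_r = hg_r, logits = logits,
                      ha = ha, ha_r = ha_r, ang = ang, B = B, T1 = T1,
                      T3 = T3, e2_dim = dim(q3$out))
  out
}

#' Joint loss and parameter gradients on one batch
#'
#' Computes `L = CE(gait) + lambda * MSE(angles)` and backpropagates through
#' every branch.
#'
#' @param model An `emg_model`.
#' @param batch As in [forward_model()], plus integer `gait` codes and
#'   `angles` targets (B x 3, degrees).
#' @return List with `loss`, `ce`, `mse`, `probs`, `pred_angles` and `grads`
#'   (parameter-shaped gradient list).
#' @export
loss_and_grads <- function(model, batch) {
  p <- model$params
  fwd <- forward_model(model, batch, keep_cache = TRUE)
  cc <- fwd$cache
  lam <- model$config$lambda

  ce <- cross_entropy(fwd$gait_logits, batch$gait)
  ms <- mse_loss(fwd$angles, batch$angles)

  g <- list()
  # gait head
  bk <- fc_backward(ce$dlogits, p$fc_gait2$W, cc$logits)
  g$fc_gait2 <- list(W = bk$dW, b = bk$db)
  dh <- relu_backward(bk$dx, cc$hg_r$mask)
  bk <- fc_backward(dh, p$fc_gait1$W, cc$hg)
  g$fc_gait1 <- list(W = bk$dW, b = bk$db)
  dfused <- bk$dx
  # angle head
  bk <- fc_backward(lam * ms$dpred, p$fc_ang2$W, cc$ang)
  g$fc_ang2 <- list(W = bk$dW, b = bk$db)
  dh <- relu_backward(bk$dx, cc$ha_r$mask)
  bk <- fc_backward(dh, p$fc_ang1$W, cc$ha)
  g$fc_ang1 <- list(W = bk$dW, b = bk$db)
  dfused <- dfused + bk$dx

  H <- model$config$gru_hidden
  d1 <- dfused[, seq_len(H), drop = FALSE]
  d2 <- dfused[, H + seq_len(ncol(dfused) - 2L * H), drop = FALSE]
  d3 <- dfused[, ncol(dfused) - H + seq_len(H), drop = FALSE]

  # branch 1: gradient enters only at the final GRU step
  dseq <- array(0, dim = dim(cc$g1$out))
  dseq[, cc$T1, ] <- d1
  gb <- gru_stack_backward(dseq, p$gru1, cc$g1)
  g$gru1 <- lapply(gb$grads, function(x)
    list(Wx = x$dWx, Wh = x$dWh, bx = x$dbx, bh = x$dbh))
  dx <- pool1d_backward(gb$dx, cc$q2)
  dx <- relu_backward(dx, cc$r2$mask)
  bk <- conv1d_backward(dx, p$conv2$W, cc$c2)
  g$conv2 <- list(W = bk$dW, b = bk$db)
  dx <- pool1d_backward(bk$dx, cc$q1)
  dx <- relu_backward(dx, cc$r1$mask)
  bk <- conv1d_backward(dx, p$conv1$W, cc$c1)
  g$conv1 <- list(W = bk$dW, b = bk$db)

  # branch 2
  dq3 <- d2
  dim(dq3) <- cc$e2_dim
  dx <- pool2d_backward(dq3, cc$q3)
  dx <- relu_backward(dx, cc$r3$mask)
  bk <- conv2d_backward(dx, p$conv2d$W, cc$c3)
  g$conv2d <- list(W = bk$dW, b = bk$db)

  # branch 3
  dseq <- array(0, dim = dim(cc$g3$out))
  dseq[, cc$T3, ] <- d3
  gb <- gru_stack_backward(dseq, p$gru3, cc$g3)
  g$gru3 <- lapply(gb$grads, function(x)
    list(Wx = x$dWx, Wh = x$dWh, bx = x$dbx, bh = x$dbh))

  list(loss = ce$loss + lam * ms$loss, ce = ce$loss, mse = ms$loss,
       probs = ce$probs, pred_angles = fwd$angles, grads = g)
}

#' Shape audit
#'
#' Runs a two-sample dummy batch through the network and asserts that every
#' declared stage shape matches the executed one; called at model build.
#'
#' @param model An `emg_model`.
#' @return `TRUE` invisibly, or an error naming the offending stage.
#' @export
audit_shapes <- function(model) {
  cfg <- model$config
  batch <- list(raw = array(0, c(2L, cfg$input_length, cfg$n_channels)),
                td = array(0, c(2L, cfg$td_dim)),
                spec = array(0, c(2L, cfg$spec_dim)))
  fwd <- forward_model(model, batch, keep_cache = TRUE)
  cc <- fwd$cache
  plan <- model$plan
  chk <- function(name, got, want) {
    if (!isTRUE(all.equal(got, want)))
      stop(sprintf("shape audit failed at %s: got %s, declared %s", name,
                   paste(got, collapse = "x"), paste(want, collapse = "x")),
           call. = FALSE)
  }
  chk("conv1", dim(cc$c1$out)[2], unname(plan["conv1"]))
  chk("pool1", dim(cc$q1$out)[2], unname(plan["pool1"]))
  chk("conv2", dim(cc$c2$out)[2], unname(plan["conv2"]))
  chk("pool2", dim(cc$q2$out)[2], unname(plan["pool2"]))
  spat <- conv2d_out_dim(cfg$spec_dim[1])
  chk("conv2d", dim(cc$c3$out)[2:3], c(spat, conv2d_out_dim(cfg$spec_dim[2])))
  chk("fusion", ncol(cc$hg$x), model$fusion_dim)
  chk("gait_logits", ncol(fwd$gait_logits), 4L)
  chk("angles", ncol(fwd$angles), 3L)
  chk("td_steps", dim(cc$g3$out)[2], cfg$td_dim[1])
  invisible(TRUE)
}

#' Predict gait probabilities and joint angles for a feature set
#'
#' @param model A trained `emg_model`.
#' @param feats An `emg_features` object (or an equivalent list of arrays).
#' @param batch_size Windows per forward pass.
#' @return List with `gait_probs` (N x 4), `gait_pred` (integer codes) and
#'   `angles` (N x 3 degrees).
#' @export
predict_model <- function(model, feats, batch_size = 256L) {
  n <- dim(feats$raw)[1]
  probs <- matrix(0, n, 4L)
  angles <- matrix(0, n, 3L, dimnames = list(NULL, joint_names()))
  for (i0 in seq.int(1L, n, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, n)
    idx <- i0:i1
    batch <- list(raw = feats$raw[idx, , , drop = FALSE],
                  td = feats$td[idx, , , drop = FALSE],
                  spec = feats$spec[idx, , , , drop = FALSE])
    fwd <- forward_model(model, batch)
    probs[idx, ] <- fwd$gait_probs
    angles[idx, ] <- fwd$angles
  }
  list(gait_probs = probs, gait_pred = max.col(probs) - 1L, angles = angles)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds weights, configuration and normalization statistics
#' (RDS); an architecture summary with a config hash is written alongside as
#' JSON.
#'
#' @param model An `emg_model`.
#' @param path Output `.rds` path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "emg_model"))
  saveRDS(model, path)
  summ <- list(config = model$config[names(model$config)],
               n_params = n_params(model),
               fusion_dim = model$fusion_dim,
               branch1_plan = as.list(model$plan),
               config_hash = config_hash(model$config))
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  model <- readRDS(path)
  stopifnot(inherits(model, "emg_model"))
  model
}

# stable hash of any config-like list (md5 of its serialized YAML)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}
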