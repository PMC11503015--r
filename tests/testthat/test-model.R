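test_that("branch 1 length arithmetic follows valid-conv and pooling rules", {
  m <- emg_model(model_config(), seed = 1)
  expect_identical(unname(m$plan),
                   c(318L, 159L, 157L, 78L))
  expect_true(audit_shapes(m))
})

test_that("embedding width is the GRU hidden size regardless of input length", {
  for (L in c(192L, 320L)) {
    cfg <- model_config(input_length = L, gru_hidden = 8L,
                        conv1_filters = 4L, conv2_filters = 8L,
                        conv2d_filters = 4L, fc_hidden = 16L)
    m <- emg_model(cfg, seed = 1)
    batch <- list(raw = array(stats::rnorm(2 * L * 8), c(2, L, 8)),
                  td = array(stats::rnorm(2 * 5 * 8), c(2, 5, 8)),
                  spec = array(stats::rnorm(2 * 9 * 9 * 8), c(2, 9, 9, 8)))
    fwd <- forward_model(m, batch)
    expect_identical(dim(fwd$gait_probs), c(2L, 4L))
    expect_identical(dim(fwd$angles), c(2L, 3L))
  }
})

test_that("gait probabilities are a proper distribution", {
  m <- emg_model(tiny_model_config(), seed = 3)
  set.seed(3)
  batch <- list(raw = array(stats::rnorm(5 * 320 * 8), c(5, 320, 8)),
                td = array(stats::rnorm(5 * 5 * 8), c(5, 5, 8)),
                spec = array(stats::rnorm(5 * 9 * 9 * 8), c(5, 9, 9, 8)))
  fwd <- forward_model(m, batch)
  expect_true(all(fwd$gait_probs >= 0))
  expect_equal(rowSums(fwd$gait_probs), rep(1, 5), tolerance = 1e-6)
  # fusion vector length is the sum of the three embedding widths
  expect_equal(m$fusion_dim, 8L + 2L * 2L * 4L + 8L)
})

test_that("zero input with zero biases gives zero conv pre-activations", {
  m <- emg_model(tiny_model_config(), seed = 4)
  m$params$conv1$b[] <- 0
  m$params$conv2d$b[] <- 0
  batch <- list(raw = array(0, c(2, 320, 8)), td = array(0, c(2, 5, 8)),
                spec = array(0, c(2, 9, 9, 8)))
  fwd <- forward_model(m, batch, keep_cache = TRUE)
  expect_true(all(fwd$cache$c1$out == 0))
  expect_true(all(fwd$cache$c3$out == 0))
  # ReLU branches therefore produce nonnegative feature maps
  expect_true(all(fwd$cache$q1$out >= 0))
})

test_that("channel permutation symmetry holds in the 2-D convolution", {
  set.seed(5)
  W <- matrix(stats::rnorm(72 * 4), 72, 4)
  b <- stats::rnorm(4)
  x <- array(stats::rnorm(2 * 9 * 9 * 8), c(2, 9, 9, 8))
  perm <- sample(8)
  xp <- x[, , , perm, drop = FALSE]
  # rows of W are 9 offset blocks of 8 channels; permute within each block
  row_perm <- as.vector(outer(perm, (0:8) * 8, `+`))
  Wp <- W[row_perm, , drop = FALSE]
  y <- conv2d_forward <- emgait:::conv2d_forward
  expect_equal(y(xp, Wp, b)$out, y(x, W, b)$out, tolerance = 1e-12)
})

test_that("shifting the input shifts the pre-GRU feature maps", {
  m <- emg_model(tiny_model_config(), seed = 6)
  set.seed(6)
  x <- stats::rnorm(340 * 8)
  dim(x) <- c(1, 340, 8)
  b1 <- list(raw = x[, 1:320, , drop = FALSE],
             td = array(0, c(1, 5, 8)), spec = array(0, c(1, 9, 9, 8)))
  b2 <- list(raw = x[, 5:324, , drop = FALSE],
             td = array(0, c(1, 5, 8)), spec = array(0, c(1, 9, 9, 8)))
  f1 <- forward_model(m, b1, keep_cache = TRUE)$cache$q2$out
  f2 <- forward_model(m, b2, keep_cache = TRUE)$cache$q2$out
  # a 4-sample input shift moves the twice-pooled maps by one step
  T2 <- dim(f1)[2]
  expect_equal(f1[, 2:T2, ], f2[, 1:(T2 - 1), ], tolerance = 1e-12)
})

test_that("the time-domain branch consumes exactly five steps", {
  m <- emg_model(tiny_model_config(), seed = 7)
  batch <- list(raw = array(0, c(2, 320, 8)),
                td = array(stats::rnorm(80), c(2, 5, 8)),
                spec = array(0, c(2, 9, 9, 8)))
  fwd <- forward_model(m, batch, keep_cache = TRUE)
  expect_identical(dim(fwd$cache$g3$out)[2], 5L)
  expect_error(forward_model(m, list(raw = batch$raw,
                                     td = array(0, c(2, 6, 8)),
                                     spec = batch$spec)))
})

test_that("the joint loss vanishes for perfect predictions", {
  logits <- matrix(c(50, 0, 0, 0,
                     0, 50, 0, 0), 2, 4, byrow = TRUE)
  ce <- emgait:::cross_entropy(logits, c(0L, 1L))
  expect_lt(ce$loss, 1e-10)
  ms <- emgait:::mse_loss(matrix(1:6, 2), matrix(1:6, 2))
  expect_identical(ms$loss, 0)
})

test_that("every trainable tensor receives gradient on a random batch", {
  m <- emg_model(tiny_model_config(), seed = 8)
  set.seed(8)
  batch <- list(raw = array(stats::rnorm(4 * 320 * 8), c(4, 320, 8)),
                td = array(stats::rnorm(4 * 5 * 8), c(4, 5, 8)),
                spec = array(stats::rnorm(4 * 9 * 9 * 8), c(4, 9, 9, 8)),
                gait = c(0L, 1L, 2L, 3L),
                angles = matrix(stats::rnorm(12, sd = 10), 4, 3))
  lg <- loss_and_grads(m, batch)
  flat <- rapply(lg$grads, function(g) sum(abs(g)), how = "unlist")
  expect_true(all(flat > 0))
})

test_that("analytic gradients match finite differences", {
  m <- emg_model(tiny_model_config(), seed = 9)
  set.seed(9)
  batch <- list(raw = array(stats::rnorm(2 * 320 * 8), c(2, 320, 8)),
                td = array(stats::rnorm(2 * 5 * 8), c(2, 5, 8)),
                spec = array(stats::rnorm(2 * 9 * 9 * 8), c(2, 9, 9, 8)),
                gait = c(1L, 3L),
                angles = matrix(stats::rnorm(6, sd = 5), 2, 3))
  lg <- loss_and_grads(m, batch)
  probe <- list(list("conv1", "W"), list("conv2d", "W"),
                list("fc_gait1", "W"), list("fc_ang2", "b"))
  for (p in probe) {
    g <- lg$grads[[p[[1]]]][[p[[2]]]]
    i <- which.max(abs(g))
    f <- function(v) {
      mm <- m
      mm$params[[p[[1]]]][[p[[2]]]][i] <- v
      loss_and_grads(mm, batch)$loss
    }
    v0 <- m$params[[p[[1]]]][[p[[2]]]][i]
    num <- (f(v0 + 1e-5) - f(v0 - 1e-5)) / 2e-5
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  # one GRU tensor from each stack
  for (br in c("gru1", "gru3")) {
    g <- lg$grads[[br]][[2]]$Wh
    i <- which.max(abs(g))
    f <- function(v) {
      mm <- m
      mm$params[[br]][[2]]$Wh[i] <- v
      loss_and_grads(mm, batch)$loss
    }
    v0 <- m$params[[br]][[2]]$Wh[i]
    num <- (f(v0 + 1e-5) - f(v0 - 1e-5)) / 2e-5
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("model construction is deterministic under a fixed seed", {
  m1 <- emg_model(tiny_model_config(), seed = 10)
  m2 <- emg_model(tiny_model_config(), seed = 10)
  expect_identical(m1$params, m2$params)
})

test_that("checkpoints round-trip with an architecture summary", {
  m <- emg_model(tiny_model_config(), seed = 11)
  path <- file.path(tempdir(), "ckpt.rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  summ <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(summ$n_params, n_params(m))
  unlink(c(path, paste0(path, ".json")))
})
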