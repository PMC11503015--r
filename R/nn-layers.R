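# Neural-network primitives with hand-written forward and backward passes.
# Batches are stored batch-major: (B, time, channels) for sequences and
# (B, height, width, channels) for spectrograms.  Each forward returns the
# output plus the cache its backward needs; backwards return the input
# gradient and the parameter gradients.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, mask) dout * mask

# ---- 1-D convolution, kernel 3, stride 1, valid (no padding) --------------

# im2col: (B, T, C) -> (B*T_out, 3*C), column blocks ordered by tap offset
im2col1d <- function(x, t_out) {
  d <- dim(x)
  blocks <- lapply(0:2, function(o) {
    s <- x[, (1L + o):(t_out + o), , drop = FALSE]
    dim(s) <- c(d[1] * t_out, d[3])
    s
  })
  do.call(cbind, blocks)
}

conv1d_forward <- function(x, W, b) {
  d <- dim(x)                       # B, T, C
  t_out <- d[2] - 2L
  if (t_out < 1L) stop("input too short for a width-3 convolution", call. = FALSE)
  m <- im2col1d(x, t_out)
  y <- sweep(m %*% W, 2L, b, "+")
  dim(y) <- c(d[1], t_out, ncol(W))
  list(out = y, m = m, in_dim = d, t_out = t_out)
}

conv1d_backward <- function(dout, W, cache) {
  d <- cache$in_dim
  t_out <- cache$t_out
  l_out <- ncol(W)
  dy <- dout
  dim(dy) <- c(d[1] * t_out, l_out)
  dW <- crossprod(cache$m, dy)
  db <- colSums(dy)
  dm <- tcrossprod(dy, W)           # (B*T_out, 3C)
  dx <- array(0, dim = d)
  c_in <- d[3]
  for (o in 0:2) {
    blk <- dm[, (o * c_in + 1L):((o + 1L) * c_in), drop = FALSE]
    dim(blk) <- c(d[1], t_out, c_in)
    dx[, (1L + o):(t_out + o), ] <- dx[, (1L + o):(t_out + o), , drop = FALSE] + blk
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- 1-D max pooling, size 2, stride 2 ------------------------------------

pool1d_forward <- function(x) {
  d <- dim(x)
  t_out <- d[2] %/% 2L
  a <- x[, 2L * seq_len(t_out) - 1L, , drop = FALSE]
  b <- x[, 2L * seq_len(t_out), , drop = FALSE]
  mask <- a >= b
  list(out = a * mask + b * !mask, mask = mask, in_dim = d, t_out = t_out)
}

pool1d_backward <- function(dout, cache) {
  d <- cache$in_dim
  t_out <- cache$t_out
  dx <- array(0, dim = d)
  dx[, 2L * seq_len(t_out) - 1L, ] <- dout * cache$mask
  dx[, 2L * seq_len(t_out), ] <- dout * !cache$mask
  dx
}

# ---- 2-D convolution, kernel 3x3, stride 2, valid -------------------------

conv2d_out_dim <- function(d) (d - 3L) %/% 2L + 1L

# im2col: (B, H, W, C) -> (B*Ho*Wo, 9*C), blocks ordered (dj, di) column-major
im2col2d <- function(x, ho, wo) {
  d <- dim(x)
  rows <- 2L * seq_len(ho) - 1L
  cols <- 2L * seq_len(wo) - 1L
  blocks <- list()
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    s <- x[, rows + di, cols + dj, , drop = FALSE]
    dim(s) <- c(d[1] * ho * wo, d[4])
    blocks[[k]] <- s
  }
  do.call(cbind, blocks)
}

conv2d_forward <- function(x, W, b) {
  d <- dim(x)                       # B, H, W, C
  ho <- conv2d_out_dim(d[2])
  wo <- conv2d_out_dim(d[3])
  m <- im2col2d(x, ho, wo)
  y <- sweep(m %*% W, 2L, b, "+")
  dim(y) <- c(d[1], ho, wo, ncol(W))
  list(out = y, m = m, in_dim = d, ho = ho, wo = wo)
}

conv2d_backward <- function(dout, W, cache) {
  d <- cache$in_dim
  ho <- cache$ho; wo <- cache$wo
  dy <- dout
  dim(dy) <- c(d[1] * ho * wo, ncol(W))
  dW <- crossprod(cache$m, dy)
  db <- colSums(dy)
  dm <- tcrossprod(dy, W)
  dx <- array(0, dim = d)
  rows <- 2L * seq_len(ho) - 1L
  cols <- 2L * seq_len(wo) - 1L
  c_in <- d[4]
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- dm[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    dim(blk) <- c(d[1], ho, wo, c_in)
    dx[, rows + di, cols + dj, ] <-
      dx[, rows + di, cols + dj, , drop = FALSE] + blk
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- 2-D max pooling, 2x2, stride 2 ---------------------------------------

pool2d_forward <- function(x) {
  d <- dim(x)
  ho <- d[2] %/% 2L; wo <- d[3] %/% 2L
  ri <- 2L * seq_len(ho) - 1L
  cj <- 2L * seq_len(wo) - 1L
  a11 <- x[, ri, cj, , drop = FALSE];      a21 <- x[, ri + 1L, cj, , drop = FALSE]
  a12 <- x[, ri, cj + 1L, , drop = FALSE]; a22 <- x[, ri + 1L, cj + 1L, , drop = FALSE]
  m11 <- a11 >= a21 & a11 >= a12 & a11 >= a22
  m21 <- !m11 & a21 >= a12 & a21 >= a22
  m12 <- !m11 & !m21 & a12 >= a22
  m22 <- !(m11 | m21 | m12)
  out <- a11 * m11 + a21 * m21 + a12 * m12 + a22 * m22
  list(out = out, masks = list(m11, m21, m12, m22), in_dim = d,
       ho = ho, wo = wo)
}

pool2d_backward <- function(dout, cache) {
  d <- cache$in_dim
  ri <- 2L * seq_len(cache$ho) - 1L
  cj <- 2L * seq_len(cache$wo) - 1L
  m <- cache$masks
  dx <- array(0, dim = d)
  dx[, ri, cj, ] <- dout * m[[1]]
  dx[, ri + 1L, cj, ] <- dout * m[[2]]
  dx[, ri, cj + 1L, ] <- dout * m[[3]]
  dx[, ri + 1L, cj + 1L, ] <- dout * m[[4]]
  dx
}

# ---- gated recurrent unit -------------------------------------------------
# Gate layout in the fused weight matrices is [reset | update | candidate]:
#   r = sigmoid(x Wx_r + bx_r + h Wh_r + bh_r)
#   z = sigmoid(x Wx_z + bx_z + h Wh_z + bh_z)
#   n = tanh(x Wx_n + bx_n + r * (h Wh_n + bh_n))
#   h' = (1 - z) * n + z * h

gru_init <- function(d_in, hidden, rng) {
  s <- 1 / sqrt(hidden)
  list(Wx = matrix(rng(d_in * 3L * hidden, s), d_in, 3L * hidden),
       Wh = matrix(rng(hidden * 3L * hidden, s), hidden, 3L * hidden),
       bx = rng(3L * hidden, s), bh = rng(3L * hidden, s))
}

# x: (B, T, D); returns full hidden sequence (B, T, H) plus caches for BPTT
gru_forward <- function(x, p) {
  d <- dim(x)
  hdim <- ncol(p$Wh)        # 3H
  H <- hdim %/% 3L
  ir <- seq_len(H); iz <- ir + H; in_ <- iz + H
  h <- matrix(0, d[1], H)
  hs <- array(0, c(d[1], d[2], H))
  cache <- vector("list", d[2])
  for (t in seq_len(d[2])) {
    xt <- x[, t, , drop = FALSE]; dim(xt) <- c(d[1], d[3])
    gx <- sweep(xt %*% p$Wx, 2L, p$bx, "+")
    gh <- sweep(h %*% p$Wh, 2L, p$bh, "+")
    r <- sigmoid(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
    z <- sigmoid(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
    ghn <- gh[, in_, drop = FALSE]
    n <- tanh(gx[, in_, drop = FALSE] + r * ghn)
    cache[[t]] <- list(xt = xt, h_prev = h, r = r, z = z, n = n, ghn = ghn)
    h <- (1 - z) * n + z * h
    hs[, t, ] <- h
  }
  list(out = hs, cache = cache, in_dim = d, H = H)
}

# dout: gradient on the full hidden sequence (B, T, H)
gru_backward <- function(dout, p, fwd) {
  d <- fwd$in_dim
  H <- fwd$H
  ir <- seq_len(H); iz <- ir + H; in_ <- iz + H
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  dbx <- numeric(3L * H); dbh <- numeric(3L * H)
  dx <- array(0, dim = d)
  dh <- matrix(0, d[1], H)
  for (t in rev(seq_len(d[2]))) {
    cc <- fwd$cache[[t]]
    dht <- dh + matrix(dout[, t, ], d[1], H)
    dz <- dht * (cc$h_prev - cc$n) * cc$z * (1 - cc$z)
    dn <- dht * (1 - cc$z) * (1 - cc$n^2)
    dr <- dn * cc$ghn * cc$r * (1 - cc$r)
    dgx <- cbind(dr, dz, dn)
    dgh <- cbind(dr, dz, dn * cc$r)
    dWx <- dWx + crossprod(cc$xt, dgx)
    dWh <- dWh + crossprod(cc$h_prev, dgh)
    dbx <- dbx + colSums(dgx)
    dbh <- dbh + colSums(dgh)
    dx[, t, ] <- tcrossprod(dgx, p$Wx)
    dh <- tcrossprod(dgh, p$Wh) + dht * cc$z
  }
  list(dx = dx, dWx = dWx, dWh = dWh, dbx = dbx, dbh = dbh)
}

# three stacked GRU layers; only shapes differ between layers
gru_stack_forward <- function(x, layers) {
  caches <- vector("list", length(layers))
  h <- x
  for (k in seq_along(layers)) {
    f <- gru_forward(h, layers[[k]])
    caches[[k]] <- f
    h <- f$out
  }
  list(out = h, caches = caches)
}

gru_stack_backward <- function(dout, layers, fwd) {
  grads <- vector("list", length(layers))
  dh <- dout
  for (k in rev(seq_along(layers))) {
    g <- gru_backward(dh, layers[[k]], fwd$caches[[k]])
    grads[[k]] <- g[c("dWx", "dWh", "dbx", "dbh")]
    dh <- g$dx
  }
  list(dx = dh, grads = grads)
}

# ---- fully connected ------------------------------------------------------

fc_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), x = x)
}

fc_backward <- function(dout, W, cache) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# ---- losses ---------------------------------------------------------------

# numerically stable softmax over rows
softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# mean cross-entropy; targets are integer class codes 0..K-1
cross_entropy <- function(logits, targets) {
  probs <- softmax(logits)
  idx <- cbind(seq_len(nrow(probs)), targets + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / nrow(probs), probs = probs)
}

# mean squared error over all entries
mse_loss <- function(pred, target) {
  diff <- pred - target
  list(loss = mean(diff^2), dpred = 2 * diff / length(diff))
}
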