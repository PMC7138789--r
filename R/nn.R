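# Minimal vectorized neural-network engine: dense, dropout, convolutional
# and transposed-convolutional layers with Glorot-uniform initialization,
# ReLU/linear activations and Adam updates. Written against base R matrix
# algebra; convolutions go through im2col/col2im gathers so every batch is
# a handful of large matrix products.
#
# Data layout conventions:
#   * dense data: B x D matrices (samples in rows);
#   * image data: B x (C * p^2) matrices, columns ordered cell-fastest
#     within channel, grid cells in column-major order of the p x p grid;
#   * conv weights W: (f^2 * in_ch) x out_ch, patch cells fastest, then
#     input channel; tconv weights V: (f^2 * out_ch) x in_ch.

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

act_forward <- function(act, z) {
  switch(act,
    linear = z,
    relu = {z[z < 0] <- 0; z},
    sigmoid = sigmoid(z))
}

# dA -> dZ given the activation output A.
act_backward <- function(act, dA, A) {
  switch(act,
    linear = dA,
    relu = dA * (A > 0),
    sigmoid = dA * A * (1 - A))
}

nn_dense <- function(n_in, n_out, act = "linear") {
  W <- glorot_uniform(n_in, n_out, n_in, n_out)
  list(type = "dense", act = act, W = W, b = numeric(n_out),
       mW = W * 0, vW = W * 0, mb = numeric(n_out), vb = numeric(n_out))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

# Gather index for im2col: rows are patch entries (cell-within-patch
# fastest, then channel), columns are output positions (column-major on the
# output grid). Values index into the flattened C x p x p input layout.
im2col_index <- function(p, f, s, n_ch) {
  o <- (p - f) %/% s + 1L
  offs_cell <- as.vector(outer(0:(f - 1L), (0:(f - 1L)) * p, "+"))
  offs <- as.vector(outer(offs_cell, (0:(n_ch - 1L)) * p * p, "+"))
  base <- as.vector(outer((0:(o - 1L)) * s, (0:(o - 1L)) * s * p, "+")) + 1L
  list(idx = outer(offs, base, "+"), out_size = o)
}

nn_conv <- function(in_ch, out_ch, f, s, in_size, act = "relu") {
  ic <- im2col_index(in_size, f, s, in_ch)
  fan_in <- f * f * in_ch
  fan_out <- f * f * out_ch
  W <- glorot_uniform(fan_in, fan_out, f * f * in_ch, out_ch)
  list(type = "conv", act = act, in_ch = in_ch, out_ch = out_ch, f = f, s = s,
       in_size = in_size, out_size = ic$out_size, idx = ic$idx,
       W = W, b = numeric(out_ch),
       mW = W * 0, vW = W * 0, mb = numeric(out_ch), vb = numeric(out_ch))
}

# Transposed convolution mirroring a conv layer of geometry (f, s) whose
# input side was `target`: output is laid on a (in_size-1)*s + f grid and
# zero-padded (bottom/right) up to `target`.
nn_tconv <- function(in_ch, out_ch, f, s, in_size, target, act = "relu") {
  full <- (in_size - 1L) * s + f
  stopifnot(full <= target)
  ic <- im2col_index(full, f, s, out_ch)
  stopifnot(ic$out_size == in_size)
  # positions of the `full` grid inside the `target` grid, per channel
  cm <- outer(seq_len(full), (seq_len(full) - 1L) * target, "+")
  map <- as.vector(outer(as.vector(cm),
                         (0:(out_ch - 1L)) * target * target, "+"))
  fan_in <- f * f * in_ch
  fan_out <- f * f * out_ch
  V <- glorot_uniform(fan_in, fan_out, f * f * out_ch, in_ch)
  list(type = "tconv", act = act, in_ch = in_ch, out_ch = out_ch, f = f,
       s = s, in_size = in_size, full = full, target = target,
       idx = ic$idx, map = map, V = V, b = numeric(out_ch),
       mW = V * 0, vW = V * 0, mb = numeric(out_ch), vb = numeric(out_ch))
}

# Scatter-add of patch gradients back onto the input grid. `cols` is a
# (B*o2) x (f2C) matrix with rows ordered b-fastest-then-position; returns
# B x (n_ch * p^2).
col2im <- function(cols, idx, B, n_cells) {
  o2 <- ncol(idx)
  f2C <- nrow(idx)
  dim(cols) <- c(B, o2, f2C)
  M <- aperm(cols, c(2L, 3L, 1L))
  dim(M) <- c(o2 * f2C, B)
  g <- as.vector(t(idx))
  rs <- rowsum(M, group = g)
  out <- matrix(0, n_cells, B)
  out[as.integer(rownames(rs)), ] <- rs
  t(out)
}

layer_forward <- function(layer, X, training = FALSE) {
  B <- nrow(X)
  switch(layer$type,
    dense = {
      Z <- X %*% layer$W
      Z <- Z + rep(layer$b, each = B)
      A <- act_forward(layer$act, Z)
      list(out = A, cache = list(X = X, A = A))
    },
    dropout = {
      if (training) {
        mask <- matrix((stats::runif(length(X)) >= layer$rate) /
                         (1 - layer$rate), B, ncol(X))
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = NULL)
      }
    },
    conv = {
      f2C <- layer$f^2 * layer$in_ch
      o2 <- layer$out_size^2
      Xc <- X[, as.vector(layer$idx), drop = FALSE]
      dim(Xc) <- c(B, f2C, o2)
      Xc <- aperm(Xc, c(1L, 3L, 2L))
      dim(Xc) <- c(B * o2, f2C)
      Z <- Xc %*% layer$W
      Z <- Z + rep(layer$b, each = B * o2)
      A <- act_forward(layer$act, Z)
      out <- A
      dim(out) <- c(B, o2 * layer$out_ch)
      list(out = out, cache = list(Xc = Xc, A = A))
    },
    tconv = {
      p2 <- layer$in_size^2
      Xm <- X
      dim(Xm) <- c(B * p2, layer$in_ch)
      P <- Xm %*% t(layer$V)
      Yfull <- col2im(P, layer$idx, B, layer$out_ch * layer$full^2)
      Y <- matrix(0, B, layer$out_ch * layer$target^2)
      Y[, layer$map] <- Yfull
      Y <- Y + rep(rep(layer$b, each = layer$target^2), each = B)
      A <- act_forward(layer$act, Y)
      list(out = A, cache = list(Xm = Xm, A = A))
    })
}

layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
    dense = {
      dZ <- act_backward(layer$act, dOut, cache$A)
      list(dX = dZ %*% t(layer$W),
           grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
    },
    dropout = {
      if (is.null(cache)) list(dX = dOut, grads = NULL)
      else list(dX = dOut * cache$mask, grads = NULL)
    },
    conv = {
      B <- nrow(dOut)
      o2 <- layer$out_size^2
      dim(dOut) <- c(B * o2, layer$out_ch)
      dZ <- act_backward(layer$act, dOut, cache$A)
      dW <- crossprod(cache$Xc, dZ)
      db <- colSums(dZ)
      dXc <- dZ %*% t(layer$W)
      dX <- col2im(dXc, layer$idx, B, layer$in_ch * layer$in_size^2)
      list(dX = dX, grads = list(W = dW, b = db))
    },
    tconv = {
      B <- nrow(dOut)
      dZ <- act_backward(layer$act, dOut, cache$A)
      t2 <- layer$target^2
      db <- colSums(matrix(colSums(dZ), t2, layer$out_ch))
      dYfull <- dZ[, layer$map, drop = FALSE]
      f2C <- layer$f^2 * layer$out_ch
      p2 <- layer$in_size^2
      dP <- dYfull[, as.vector(layer$idx), drop = FALSE]
      dim(dP) <- c(B, f2C, p2)
      dP <- aperm(dP, c(1L, 3L, 2L))
      dim(dP) <- c(B * p2, f2C)
      dXm <- dP %*% layer$V
      dim(dXm) <- c(B, p2 * layer$in_ch)
      list(dX = dXm, grads = list(W = crossprod(dP, cache$Xm), b = db))
    })
}

net_forward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    fw <- layer_forward(net[[i]], X, training = training)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    bw <- layer_backward(net[[i]], caches[[i]], dOut)
    dOut <- bw$dX
    grads[i] <- list(bw$grads)  # keep NULL slots (parameter-free layers)
  }
  list(dX = dOut, grads = grads)
}

adam_update <- function(layer, g, t, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  wname <- if (layer$type == "tconv") "V" else "W"
  layer$mW <- beta1 * layer$mW + (1 - beta1) * g$W
  layer$vW <- beta2 * layer$vW + (1 - beta2) * g$W^2
  layer$mb <- beta1 * layer$mb + (1 - beta1) * g$b
  layer$vb <- beta2 * layer$vb + (1 - beta2) * g$b^2
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  layer[[wname]] <- layer[[wname]] -
    lr * (layer$mW / c1) / (sqrt(layer$vW / c2) + eps)
  layer$b <- layer$b - lr * (layer$mb / c1) / (sqrt(layer$vb / c2) + eps)
  layer
}

net_update <- function(net, grads, t, lr) {
  for (i in seq_along(net)) {
    if (!is.null(grads[[i]])) {
      net[[i]] <- adam_update(net[[i]], grads[[i]], t, lr)
    }
  }
  net
}

# Mini-batch index blocks for one epoch (pre-shuffled order).
batch_blocks <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
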