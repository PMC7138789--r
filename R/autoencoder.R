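#' Variational autoencoder objective
#'
#' Evaluates the (negative ELBO) training objective for a single input and
#' its encoder/decoder outputs: a squared-error reconstruction term plus
#' the closed-form KL divergence between the diagonal-Gaussian posterior
#' `N(mu, diag(exp(log_var)))` and the standard-normal prior,
#' `KL = -1/2 * sum(1 + log_var - mu^2 - exp(log_var))`. The KL term is
#' non-negative and zero exactly when `mu = 0`, `log_var = 0`.
#'
#' @param x Input vector.
#' @param outputs List with elements `mu`, `log_var` (latent vectors) and
#'   `reconstruction` (vector of `length(x)`).
#' @return List with `total_loss`, `reconstruction_term`, `kl_term`.
#' @export
vae_objective <- function(x, outputs) {
  mu <- outputs$mu
  lv <- outputs$log_var
  if (length(mu) != length(lv)) me_stop("mu and log_var lengths differ")
  if (length(outputs$reconstruction) != length(x)) {
    me_stop("reconstruction length must match input length")
  }
  recon <- sum((x - outputs$reconstruction)^2)
  kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv))
  list(total_loss = recon + kl, reconstruction_term = recon, kl_term = kl)
}

# ---- network builders ------------------------------------------------------

build_dense_ae <- function(arch) {
  widths <- dae_layer_schedule(arch$latent_dim, arch$n_added_layers)
  dims <- c(arch$input_dim, widths, arch$input_dim)
  latent_pos <- arch$n_added_layers + 1L  # index into `widths`
  net <- vector("list", length(dims) - 1L)
  for (i in seq_along(net)) {
    # latent and output layers are linear; inserted layers are ReLU
    act <- if (i == latent_pos || i == length(net)) "linear" else "relu"
    net[[i]] <- nn_dense(dims[i], dims[i + 1L], act = act)
  }
  list(net = net, n_encoder_layers = latent_pos)
}

build_vae <- function(arch) {
  k <- arch$latent_dim
  list(enc = list(nn_dense(arch$input_dim, arch$intermediate_units, "relu"),
                  nn_dense(arch$intermediate_units, 2L * k, "linear")),
       dec = list(nn_dense(k, arch$intermediate_units, "relu"),
                  nn_dense(arch$intermediate_units, arch$input_dim, "linear")))
}

build_cae <- function(arch) {
  d <- square_grid_dim(arch$input_dim)
  geom <- cae_geometry(d, arch$n_conv_layers)
  filters <- cae_filter_schedule(arch$first_filters, arch$n_conv_layers)
  chans <- c(1L, filters)
  sizes <- c(d, vapply(geom, `[[`, integer(1), "output_size"))
  enc <- lapply(seq_len(arch$n_conv_layers), function(k)
    nn_conv(chans[k], chans[k + 1L], geom[[k]]$filter_size, geom[[k]]$stride,
            sizes[k], act = "relu"))
  dec <- lapply(rev(seq_len(arch$n_conv_layers)), function(k)
    nn_tconv(chans[k + 1L], chans[k], geom[[k]]$filter_size, geom[[k]]$stride,
             sizes[k + 1L], target = sizes[k],
             act = if (k == 1L) "linear" else "relu"))
  # feature j of the input vector sits at row-major cell j of the d x d grid
  j <- seq_len(arch$input_dim) - 1L
  img_idx <- (j %% d) * d + (j %/% d) + 1L
  list(net = c(enc, dec), n_encoder_layers = arch$n_conv_layers,
       grid_dim = d, img_idx = img_idx,
       latent_dim = filters[arch$n_conv_layers] *
         sizes[arch$n_conv_layers + 1L]^2)
}

cae_to_image <- function(X, d, img_idx) {
  img <- matrix(0, nrow(X), d * d)
  img[, img_idx] <- X
  img
}

# ---- training --------------------------------------------------------------

#' Train an autoencoder and return its encoder
#'
#' Optimizes mean-squared-error reconstruction (for the VAE, the squared
#' error plus KL objective of [vae_objective()]) with Adam (learning rate
#' 0.001, epsilon 1e-7), mini-batches of `batch_size`, Glorot-uniform
#' initial weights, and early stopping: training halts once the validation
#' reconstruction loss has not improved for `patience` consecutive epochs
#' (or at `max_epochs`), and the weights of the epoch with the minimum
#' validation loss are restored.
#'
#' @param arch An [ae_architecture()]; `arch$input_dim` must equal the
#'   number of columns of the data.
#' @param train Training rows (matrix or [profile_matrix()]).
#' @param validation Validation rows on the same feature space; used only
#'   for early stopping, never for gradient updates.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and (for the VAE) the reparameterization noise. Identical
#'   inputs and seed reproduce the run exactly.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on epochs; early stopping normally halts
#'   training well before it.
#' @param patience Early-stopping patience in epochs.
#' @param learning_rate Adam step size.
#' @return An object of class `trained_encoder`; see [encode()].
#' @export
train_autoencoder <- function(arch, train, validation, seed = 0L,
                              batch_size = 32L, max_epochs = 2000L,
                              patience = 20L, learning_rate = 1e-3) {
  stopifnot(inherits(arch, "ae_architecture"))
  Xtr <- as_feature_matrix(train)
  Xva <- as_feature_matrix(validation)
  if (ncol(Xtr) != arch$input_dim || ncol(Xva) != arch$input_dim) {
    me_stop("data feature count does not match arch$input_dim")
  }
  with_seed(seed, {
    switch(arch$kind,
      SAE = ,
      DAE = fit_dense_ae(arch, Xtr, Xva, batch_size, max_epochs, patience,
                         learning_rate),
      VAE = fit_vae(arch, Xtr, Xva, batch_size, max_epochs, patience,
                    learning_rate),
      CAE = fit_cae(arch, Xtr, Xva, batch_size, max_epochs, patience,
                    learning_rate))
  })
}

# Shared early-stopping loop. `step_fn(state, idx)` performs one mini-batch
# update and returns list(state, loss); `val_fn(state)` returns the
# validation loss; `snapshot(state)` extracts the parameters to keep.
early_stopping_loop <- function(state, n_train, step_fn, val_fn, snapshot,
                                batch_size, max_epochs, patience) {
  best_val <- Inf
  best_epoch <- 0L
  best_params <- NULL
  log_train <- numeric(0)
  log_val <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    blocks <- batch_blocks(n_train, batch_size)
    losses <- numeric(length(blocks))
    for (bi in seq_along(blocks)) {
      res <- step_fn(state, blocks[[bi]])
      state <- res$state
      losses[bi] <- res$loss
    }
    tr_loss <- mean(losses)
    va_loss <- val_fn(state)
    if (!is.finite(tr_loss) || !is.finite(va_loss)) {
      me_stop("non-finite loss at epoch ", epoch,
              class = "microembed_training_error")
    }
    log_train <- c(log_train, tr_loss)
    log_val <- c(log_val, va_loss)
    if (va_loss < best_val) {           # strict: earliest epoch wins ties
      best_val <- va_loss
      best_epoch <- epoch
      best_params <- snapshot(state)
    }
    if (epoch - best_epoch >= patience) break
  }
  list(params = best_params, best_epoch = best_epoch,
       log = data.frame(epoch = seq_along(log_train),
                        train_loss = log_train, val_loss = log_val))
}

fit_dense_ae <- function(arch, Xtr, Xva, batch_size, max_epochs, patience,
                         lr) {
  built <- build_dense_ae(arch)
  state <- list(net = built$net, t = 0L)
  step_fn <- function(state, idx) {
    Xb <- Xtr[idx, , drop = FALSE]
    fw <- net_forward(state$net, Xb, training = TRUE)
    resid <- fw$out - Xb
    loss <- mean(resid^2)
    bw <- net_backward(state$net, fw$caches, 2 * resid / length(resid))
    state$t <- state$t + 1L
    state$net <- net_update(state$net, bw$grads, state$t, lr)
    list(state = state, loss = loss)
  }
  val_fn <- function(state) {
    mean((net_forward(state$net, Xva)$out - Xva)^2)
  }
  fit <- early_stopping_loop(state, nrow(Xtr), step_fn, val_fn,
                             function(s) s$net, batch_size, max_epochs,
                             patience)
  new_trained_encoder(arch,
                      enc_layers = fit$params[seq_len(built$n_encoder_layers)],
                      dec_layers = fit$params[-seq_len(built$n_encoder_layers)],
                      latent_dim = arch$latent_dim,
                      training_log = fit$log, best_epoch = fit$best_epoch)
}

fit_vae <- function(arch, Xtr, Xva, batch_size, max_epochs, patience, lr) {
  k <- arch$latent_dim
  nets <- build_vae(arch)
  state <- list(enc = nets$enc, dec = nets$dec, t = 0L)
  vae_forward <- function(state, Xb, eps = NULL) {
    fe <- net_forward(state$enc, Xb, training = !is.null(eps))
    mu <- fe$out[, seq_len(k), drop = FALSE]
    lv <- fe$out[, k + seq_len(k), drop = FALSE]
    z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
    fd <- net_forward(state$dec, z, training = !is.null(eps))
    list(fe = fe, fd = fd, mu = mu, lv = lv, xhat = fd$out)
  }
  batch_loss <- function(fw, Xb) {
    recon <- sum((Xb - fw$xhat)^2)
    kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv))
    (recon + kl) / nrow(Xb)
  }
  step_fn <- function(state, idx) {
    Xb <- Xtr[idx, , drop = FALSE]
    B <- nrow(Xb)
    eps <- matrix(stats::rnorm(B * k), B, k)
    fw <- vae_forward(state, Xb, eps)
    loss <- batch_loss(fw, Xb)
    dxhat <- 2 * (fw$xhat - Xb) / B
    bw_dec <- net_backward(state$dec, fw$fd$caches, dxhat)
    dz <- bw_dec$dX
    dmu <- dz + fw$mu / B
    dlv <- dz * eps * 0.5 * exp(0.5 * fw$lv) + 0.5 * (exp(fw$lv) - 1) / B
    bw_enc <- net_backward(state$enc, fw$fe$caches, cbind(dmu, dlv))
    state$t <- state$t + 1L
    state$dec <- net_update(state$dec, bw_dec$grads, state$t, lr)
    state$enc <- net_update(state$enc, bw_enc$grads, state$t, lr)
    list(state = state, loss = loss)
  }
  # validation loss is evaluated at the posterior mean (z = mu): a
  # deterministic early-stopping signal
  val_fn <- function(state) batch_loss(vae_forward(state, Xva), Xva)
  fit <- early_stopping_loop(state, nrow(Xtr), step_fn, val_fn,
                             function(s) list(enc = s$enc, dec = s$dec),
                             batch_size, max_epochs, patience)
  new_trained_encoder(arch, enc_layers = fit$params$enc,
                      dec_layers = fit$params$dec, latent_dim = k,
                      training_log = fit$log, best_epoch = fit$best_epoch)
}

fit_cae <- function(arch, Xtr, Xva, batch_size, max_epochs, patience, lr) {
  built <- build_cae(arch)
  Itr <- cae_to_image(Xtr, built$grid_dim, built$img_idx)
  Iva <- cae_to_image(Xva, built$grid_dim, built$img_idx)
  state <- list(net = built$net, t = 0L)
  step_fn <- function(state, idx) {
    Xb <- Itr[idx, , drop = FALSE]
    fw <- net_forward(state$net, Xb, training = TRUE)
    resid <- fw$out - Xb
    loss <- mean(resid^2)
    bw <- net_backward(state$net, fw$caches, 2 * resid / length(resid))
    state$t <- state$t + 1L
    state$net <- net_update(state$net, bw$grads, state$t, lr)
    list(state = state, loss = loss)
  }
  val_fn <- function(state) {
    mean((net_forward(state$net, Iva)$out - Iva)^2)
  }
  fit <- early_stopping_loop(state, nrow(Xtr), step_fn, val_fn,
                             function(s) s$net, batch_size, max_epochs,
                             patience)
  new_trained_encoder(arch,
                      enc_layers = fit$params[seq_len(built$n_encoder_layers)],
                      dec_layers = fit$params[-seq_len(built$n_encoder_layers)],
                      latent_dim = built$latent_dim,
                      training_log = fit$log, best_epoch = fit$best_epoch,
                      extra = list(grid_dim = built$grid_dim,
                                   img_idx = built$img_idx))
}

new_trained_encoder <- function(arch, enc_layers, dec_layers, latent_dim,
                                training_log, best_epoch, extra = NULL) {
  structure(list(architecture = arch, enc_layers = enc_layers,
                 dec_layers = dec_layers, latent_dim = as.integer(latent_dim),
                 input_dim = arch$input_dim, training_log = training_log,
                 best_epoch = as.integer(best_epoch), extra = extra),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("<trained_encoder> %s: %d -> %d, best epoch %d/%d (val loss %.4g)\n",
              format(x$architecture), x$input_dim, x$latent_dim,
              x$best_epoch, nrow(x$training_log),
              x$training_log$val_loss[x$best_epoch]))
  invisible(x)
}

#' Map profiles to their latent representation
#'
#' Applies the encoder half of a trained autoencoder. Deterministic and
#' side-effect free: for the VAE the posterior mean `mu` is returned (no
#' sampling); for the CAE the output is the flattened last encoder
#' convolutional layer.
#'
#' @param encoder A `trained_encoder` from [train_autoencoder()].
#' @param data Matrix or [profile_matrix()] rows on the training feature
#'   space.
#' @return A numeric matrix, `nrow(data)` x `encoder$latent_dim`.
#' @export
encode <- function(encoder, data) {
  stopifnot(inherits(encoder, "trained_encoder"))
  X <- as_feature_matrix(data)
  if (ncol(X) != encoder$input_dim) {
    me_stop("data has ", ncol(X), " features; encoder expects ",
            encoder$input_dim)
  }
  kind <- encoder$architecture$kind
  if (kind == "CAE") {
    X <- cae_to_image(X, encoder$extra$grid_dim, encoder$extra$img_idx)
  }
  out <- net_forward(encoder$enc_layers, X)$out
  if (kind == "VAE") {
    out <- out[, seq_len(encoder$latent_dim), drop = FALSE]
  }
  out
}

#' Reconstruct profiles through a trained autoencoder
#'
#' Runs the full encoder-decoder pass (for the VAE, through the posterior
#' mean). Mainly useful for inspecting reconstruction quality.
#'
#' @inheritParams encode
#' @return Matrix of reconstructed inputs (CAE: the zero-padded square
#'   image is cropped back to the original feature order).
#' @export
reconstruct <- function(encoder, data) {
  z <- encode(encoder, data)
  out <- net_forward(encoder$dec_layers, z)$out
  if (encoder$architecture$kind == "CAE") {
    out <- out[, encoder$extra$img_idx, drop = FALSE]
  }
  out
}

#' Save or load a trained encoder
#'
#' Serializes the architecture description, weights and training log to a
#' single file for later encode-only use.
#'
#' @param encoder A `trained_encoder`.
#' @param path File path.
#' @return `save_encoder`: `path`, invisibly; `load_encoder`: the encoder.
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "trained_encoder"))
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  enc <- readRDS(path)
  if (!inherits(enc, "trained_encoder")) me_stop("not a trained encoder file")
  enc
}

as_feature_matrix <- function(x) {
  if (inherits(x, "profile_matrix")) x <- profile_values(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}
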