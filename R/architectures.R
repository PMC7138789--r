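#' Autoencoder architecture description
#'
#' A fully resolved autoencoder design. Four families are supported:
#' `SAE` (shallow: input, latent, output, all linear), `DAE` (deep: 1 or 2
#' ReLU layers inserted symmetrically on each side of the latent layer,
#' widths doubling outward), `VAE` (variational: one ReLU intermediate
#' layer, diagonal-Gaussian latent posterior) and `CAE` (convolutional:
#' the input reshaped to a zero-padded square image, 2 or 3 conv layers
#' whose filter counts halve and whose kernel/stride sizes are fractions of
#' the running image size, mirrored by transposed convolutions).
#'
#' @param kind One of `"SAE"`, `"DAE"`, `"VAE"`, `"CAE"`.
#' @param input_dim Number of input features.
#' @param latent_dim Latent width (SAE/DAE: one of 32/64/128/256/512 in the
#'   default grid; VAE: 4, 8 or 16). Ignored for CAE, whose representation
#'   is the flattened last encoder conv layer.
#' @param n_added_layers DAE only: hidden layers inserted per side (1 or 2;
#'   0 degenerates to the SAE topology).
#' @param intermediate_units VAE only: width of the single intermediate
#'   layer.
#' @param n_conv_layers CAE only: number of encoder conv layers (2 or 3).
#' @param first_filters CAE only: filter count of the first conv layer;
#'   subsequent layers halve it.
#' @return An object of class `ae_architecture`.
#' @seealso [enumerate_ae_grid()], [train_autoencoder()]
#' @export
ae_architecture <- function(kind = c("SAE", "DAE", "VAE", "CAE"), input_dim,
                            latent_dim = NULL, n_added_layers = 0L,
                            intermediate_units = NULL, n_conv_layers = NULL,
                            first_filters = NULL) {
  kind <- match.arg(kind)
  if (!is_count(input_dim)) me_stop("input_dim must be a positive integer")
  arch <- list(kind = kind, input_dim = as.integer(input_dim),
               latent_dim = if (!is.null(latent_dim)) as.integer(latent_dim),
               n_added_layers = as.integer(n_added_layers),
               intermediate_units = if (!is.null(intermediate_units))
                 as.integer(intermediate_units),
               n_conv_layers = if (!is.null(n_conv_layers))
                 as.integer(n_conv_layers),
               first_filters = if (!is.null(first_filters))
                 as.integer(first_filters))
  switch(kind,
    SAE = {
      if (!is_count(arch$latent_dim)) me_stop("SAE requires latent_dim")
      if (arch$n_added_layers != 0L) me_stop("SAE has no added layers")
    },
    DAE = {
      if (!is_count(arch$latent_dim)) me_stop("DAE requires latent_dim")
      if (!arch$n_added_layers %in% 1:2) {
        me_stop("DAE inserts 1 or 2 layers per side")
      }
    },
    VAE = {
      if (!is_count(arch$latent_dim)) me_stop("VAE requires latent_dim")
      if (!is_count(arch$intermediate_units)) {
        me_stop("VAE requires intermediate_units")
      }
    },
    CAE = {
      if (!is_count(arch$n_conv_layers, min = 2L)) {
        me_stop("CAE requires n_conv_layers >= 2")
      }
      if (!is_count(arch$first_filters)) me_stop("CAE requires first_filters")
      # Fails here if the halving schedule would reach zero filters.
      cae_filter_schedule(arch$first_filters, arch$n_conv_layers)
    })
  structure(arch, class = "ae_architecture")
}

#' @export
print.ae_architecture <- function(x, ...) {
  cat("<ae_architecture>", format(x), "\n")
  invisible(x)
}

#' @export
format.ae_architecture <- function(x, ...) {
  switch(x$kind,
    SAE = sprintf("SAE(latent=%d)", x$latent_dim),
    DAE = sprintf("DAE(latent=%d, added=%d)", x$latent_dim, x$n_added_layers),
    VAE = sprintf("VAE(latent=%d, intermediate=%d)", x$latent_dim,
                  x$intermediate_units),
    CAE = sprintf("CAE(conv_layers=%d, first_filters=%d)", x$n_conv_layers,
                  x$first_filters))
}

#' Enumerate the autoencoder architecture grid
#'
#' Returns the default search grid of a family, in a fixed order:
#' SAE sweeps latent width over 32/64/128/256/512 (5 designs); DAE crosses
#' the same latent widths with 1 or 2 inserted layers per side (10); VAE
#' crosses intermediate widths 32/64/128/256/512 with latent 4/8/16 (15);
#' CAE crosses 2 or 3 conv layers with first-layer filter counts
#' 4/8/16/32/64 (10).
#'
#' @param kind Autoencoder family.
#' @param input_dim Number of input features of the dataset at hand.
#' @return List of [ae_architecture()] objects.
#' @export
enumerate_ae_grid <- function(kind = c("SAE", "DAE", "VAE", "CAE"), input_dim) {
  kind <- match.arg(kind)
  latents <- c(32L, 64L, 128L, 256L, 512L)
  switch(kind,
    SAE = lapply(latents, function(l)
      ae_architecture("SAE", input_dim, latent_dim = l)),
    DAE = {
      g <- expand.grid(latent = latents, added = 1:2)
      lapply(seq_len(nrow(g)), function(i)
        ae_architecture("DAE", input_dim, latent_dim = g$latent[i],
                        n_added_layers = g$added[i]))
    },
    VAE = {
      g <- expand.grid(latent = c(4L, 8L, 16L),
                       intermediate = latents)
      lapply(seq_len(nrow(g)), function(i)
        ae_architecture("VAE", input_dim, latent_dim = g$latent[i],
                        intermediate_units = g$intermediate[i]))
    },
    CAE = {
      g <- expand.grid(filters = c(4L, 8L, 16L, 32L, 64L), layers = 2:3)
      lapply(seq_len(nrow(g)), function(i)
        ae_architecture("CAE", input_dim, n_conv_layers = g$layers[i],
                        first_filters = g$filters[i]))
    })
}

#' Hidden-layer width schedule of a deep autoencoder
#'
#' Symmetric (palindromic) list of hidden-layer widths centred on the
#' latent layer; each step outward from the latent layer doubles the width.
#' `n_added_layers = 0` degenerates to the single latent layer (the SAE
#' topology).
#'
#' @param latent_dim Width of the latent layer.
#' @param n_added_layers Hidden layers inserted on each side.
#' @return Integer vector of length `2 * n_added_layers + 1`,
#'   encoder-to-decoder order.
#' @examples
#' dae_layer_schedule(512, 2) # 2048 1024 512 1024 2048
#' @export
dae_layer_schedule <- function(latent_dim, n_added_layers) {
  if (!is_count(latent_dim)) me_stop("latent_dim must be a positive integer")
  if (!is_count(n_added_layers, min = 0L)) {
    me_stop("n_added_layers must be a non-negative integer")
  }
  enc <- latent_dim * 2^(n_added_layers:0)
  as.integer(c(enc, rev(enc)[-1L]))
}

#' Reshape a feature vector to a zero-padded square grid
#'
#' Maps an `n`-vector to a `d x d` grid with `d = floor(sqrt(n)) + 1`,
#' filling row-major and zero-padding the remaining `d^2 - n` cells. This
#' is how tabular profiles are presented to the convolutional autoencoder.
#'
#' @param x Numeric vector.
#' @return A `d x d` numeric matrix.
#' @seealso [flatten_from_square()] for the exact inverse on the first
#'   `n` cells.
#' @export
reshape_to_square <- function(x) {
  n <- length(x)
  if (n < 1L) me_stop("x must be non-empty")
  d <- square_grid_dim(n)
  matrix(c(x, numeric(d * d - n)), nrow = d, ncol = d, byrow = TRUE)
}

#' Recover a feature vector from its square-grid form
#'
#' @param grid A square matrix produced by [reshape_to_square()].
#' @param n Original vector length.
#' @return Numeric vector of length `n`.
#' @export
flatten_from_square <- function(grid, n) {
  v <- as.vector(t(grid))
  v[seq_len(n)]
}

square_grid_dim <- function(n) as.integer(floor(sqrt(n)) + 1)

#' Filter-count schedule of a convolutional autoencoder encoder
#'
#' Each encoder conv layer has half the filters of the preceding one
#' (integer division), starting from `first_filters`.
#'
#' @param first_filters Filters in the first conv layer.
#' @param n_conv_layers Number of encoder conv layers.
#' @return Integer vector of length `n_conv_layers`.
#' @examples
#' cae_filter_schedule(64, 3) # 64 32 16
#' @export
cae_filter_schedule <- function(first_filters, n_conv_layers) {
  if (!is_count(first_filters)) me_stop("first_filters must be positive")
  if (!is_count(n_conv_layers)) me_stop("n_conv_layers must be positive")
  sched <- first_filters %/% 2^(seq_len(n_conv_layers) - 1L)
  if (any(sched < 1L)) {
    me_stop("filter schedule reaches zero filters: first_filters too small ",
            "for ", n_conv_layers, " conv layers",
            class = "microembed_config_error")
  }
  as.integer(sched)
}

#' Kernel and stride geometry of the CAE encoder
#'
#' The first conv layer uses a square kernel of 10% of the input width
#' (floored, minimum 1) and a stride of 25% of that kernel; each subsequent
#' layer uses 10% of the preceding layer's output size as kernel and 50% of
#' that kernel as stride (all floored, minimum 1). Output sizes follow
#' no-padding convolution arithmetic `floor((in - filter)/stride) + 1`.
#'
#' @param input_d Side length of the (square) input image; must be >= 10.
#' @param n_conv_layers Number of encoder conv layers.
#' @return A list with one element per layer:
#'   `list(filter_size, stride, output_size)`.
#' @export
cae_geometry <- function(input_d, n_conv_layers) {
  if (!is_count(input_d, min = 10L)) {
    me_stop("CAE requires an input grid of side >= 10 (input_d = ", input_d,
            ")", class = "microembed_config_error")
  }
  if (!is_count(n_conv_layers)) me_stop("n_conv_layers must be positive")
  layers <- vector("list", n_conv_layers)
  size <- as.integer(input_d)
  for (k in seq_len(n_conv_layers)) {
    f <- max(1L, as.integer(floor(0.1 * size)))
    s <- if (k == 1L) max(1L, as.integer(floor(0.25 * f)))
         else max(1L, as.integer(floor(0.5 * f)))
    out <- as.integer(floor((size - f) / s) + 1L)
    if (out < 1L) {
      me_stop("conv layer ", k, " collapses to output size < 1",
              class = "microembed_config_error")
    }
    layers[[k]] <- list(filter_size = f, stride = s, output_size = out)
    size <- out
  }
  layers
}
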