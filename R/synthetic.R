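#' Specification of a synthetic microbiome dataset
#'
#' Describes a dataset with planted low-dimensional class structure that
#' emulates the two real profile types: sparse binary marker profiles and
#' compositional abundance profiles. Samples carry a latent factor vector;
#' the disease label is a noisy threshold of a linear read-out of the
#' factors; features observe the factors (and, through a separate latent
#' direction, the label) so that the class signal lives in a low-dimensional
#' subspace an autoencoder can recover.
#'
#' @param n_samples Number of samples.
#' @param n_features Number of features (must exceed `latent_dim`).
#' @param latent_dim Dimension of the planted latent factor space.
#' @param effect_size Non-negative class-separation scale: the magnitude of
#'   the shift, along one latent direction, that the patient class imprints
#'   on the features. `0` means the features carry no label information.
#' @param sparsity Target overall fraction of 1s for marker profiles
#'   (ignored for abundance profiles).
#' @param kind `"marker"` or `"abundance"`.
#' @param seed Integer RNG seed; the same spec always generates the same
#'   dataset, bit for bit.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_synthetic()]
#' @export
synthetic_spec <- function(n_samples, n_features, latent_dim = 8,
                           effect_size = 1, sparsity = 0.1,
                           kind = c("marker", "abundance"), seed = 0L) {
  kind <- match.arg(kind)
  if (!is_count(n_samples)) me_stop("n_samples must be a positive integer")
  if (!is_count(n_features)) me_stop("n_features must be a positive integer")
  if (!is_count(latent_dim)) me_stop("latent_dim must be a positive integer")
  if (latent_dim >= n_features) me_stop("latent_dim must be < n_features")
  if (!is.numeric(effect_size) || effect_size < 0) {
    me_stop("effect_size must be non-negative")
  }
  if (kind == "marker" && (sparsity <= 0 || sparsity >= 1)) {
    me_stop("sparsity must lie in (0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 latent_dim = as.integer(latent_dim),
                 effect_size = as.numeric(effect_size),
                 sparsity = as.numeric(sparsity),
                 kind = kind, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic profile matrix with planted class structure
#'
#' Draws latent factors `z ~ N(0, I_k)` per sample and sets the label to
#' `1(w'z + e > 0)` for a fixed random unit direction `w` and standard
#' normal noise `e` (so labels stay roughly balanced and are never a
#' deterministic function of the features). Features observe
#' `t = z_perp + effect_size * label * u`, where `z_perp` is the component
#' of `z` orthogonal to `w` and `u` is a fixed unit direction: with
#' `effect_size = 0` the features are exactly independent of the label.
#'
#' Marker kind: feature `i` is Bernoulli with success probability
#' `sigmoid(a_i' t + b_i)`, with unit-norm loading rows `a_i` and intercepts
#' `b_i = b0 + spread_i`; the common offset `b0` is calibrated by bisection
#' so the realized fraction of 1s matches `sparsity`. Abundance kind: each
#' row is `softmax(A t + noise)`, hence non-negative and summing to 1.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `profiles` (a [profile_matrix()]) and
#'   `labels` (integer 0/1 vector, 1 = patient).
#' @examples
#' d <- generate_synthetic(synthetic_spec(60, 100, kind = "abundance", seed = 1))
#' range(rowSums(d$profiles)) # 1 1
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features; k <- spec$latent_dim
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * k), n, k)
    w <- stats::rnorm(k); w <- w / sqrt(sum(w^2))
    labels <- as.integer(drop(z %*% w) + stats::rnorm(n) > 0)
    # Remove the labelling direction from the factors seen by the features,
    # then re-inject the label along an independent latent direction u
    # scaled by effect_size.
    z_perp <- z - outer(drop(z %*% w), w)
    u <- stats::rnorm(k); u <- u / sqrt(sum(u^2))
    t_lat <- z_perp + spec$effect_size * outer(labels, u)
    A <- matrix(stats::rnorm(k * p), k, p)
    A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")      # unit-norm loadings
    eta <- t_lat %*% A
    if (spec$kind == "marker") {
      b_spread <- stats::rnorm(p)
      b0 <- calibrate_sparsity(eta, b_spread, spec$sparsity)
      prob <- sigmoid(sweep(eta, 2L, b_spread + b0, "+"))
      vals <- matrix(as.numeric(stats::runif(n * p) < prob), n, p)
    } else {
      eta <- eta + matrix(stats::rnorm(n * p, sd = 0.5), n, p)
      ex <- exp(eta - apply(eta, 1L, max))
      vals <- ex / rowSums(ex)
    }
    list(profiles = profile_matrix(vals, kind = spec$kind),
         labels = stats::setNames(labels, paste0("S", seq_len(n))))
  })
}

# Bisect a common intercept offset so that the mean Bernoulli probability
# over all (sample, feature) cells equals the target sparsity.
calibrate_sparsity <- function(eta, b_spread, sparsity) {
  mean_rate <- function(b0) mean(sigmoid(sweep(eta, 2L, b_spread + b0, "+")))
  lo <- -30; hi <- 30
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (mean_rate(mid) < sparsity) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
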