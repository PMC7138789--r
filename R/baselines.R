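#' PCA dimensionality reduction at a fixed explained-variance target
#'
#' Fits principal components on the training rows only and keeps the
#' smallest number of components whose cumulative explained-variance ratio
#' reaches `variance` (default 99%). The train-fitted centering and axes
#' are then applied unchanged to the other rows, so no test information
#' leaks into the projection.
#'
#' @param train Training rows (matrix or [profile_matrix()]).
#' @param other Rows to co-project with the train-fitted axes (e.g. the
#'   test set); may be `NULL`.
#' @param variance Cumulative explained-variance target in (0, 1\].
#' @return List with `train`, `other` (projected matrices),
#'   `n_components`, and `explained_variance_ratio`.
#' @export
pca_reduce <- function(train, other = NULL, variance = 0.99) {
  Xtr <- as_feature_matrix(train)
  fit <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  ratio <- ev / sum(ev)
  k <- which(cumsum(ratio) >= variance - 1e-12)[1L]
  if (is.na(k)) k <- length(ratio)
  proj <- function(X) {
    if (is.null(X)) return(NULL)
    X <- as_feature_matrix(X)
    sweep(X, 2L, fit$center) %*% fit$rotation[, seq_len(k), drop = FALSE]
  }
  list(train = fit$x[, seq_len(k), drop = FALSE], other = proj(other),
       n_components = as.integer(k), explained_variance_ratio = ratio)
}

#' Minimum dimension from the Johnson-Lindenstrauss bound
#'
#' `floor(4 * ln(n) / (eps^2/2 - eps^3/3))`: the standard bound on the
#' number of dimensions needed so that a random projection preserves all
#' pairwise distances among `n` points within a factor `(1 +/- eps)`.
#'
#' @param n_samples Number of points.
#' @param eps Distortion tolerance in (0, 1).
#' @return Integer dimension.
#' @export
jl_min_dim <- function(n_samples, eps = 0.5) {
  if (!is_count(n_samples, min = 2L)) me_stop("n_samples must be >= 2")
  if (eps <= 0 || eps >= 1) me_stop("eps must lie in (0, 1)")
  as.integer(floor(4 * log(n_samples) / (eps^2 / 2 - eps^3 / 3)))
}

#' Gaussian random-projection reduction
#'
#' Projects the data with a seeded Gaussian random matrix (entries
#' `N(0, 1/k)`); the target dimension `k` is chosen automatically from the
#' Johnson-Lindenstrauss bound at distortion `eps` for the number of
#' training rows. The same projection is applied to both row sets. When the
#' JL dimension is not smaller than the input dimension the data are passed
#' through unchanged, with a warning.
#'
#' @inheritParams pca_reduce
#' @param eps JL distortion tolerance.
#' @param seed Integer seed for the projection matrix.
#' @return List with `train`, `other`, `n_components`.
#' @export
rp_reduce <- function(train, other = NULL, eps = 0.5, seed = 0L) {
  Xtr <- as_feature_matrix(train)
  k <- jl_min_dim(nrow(Xtr), eps)
  p <- ncol(Xtr)
  if (k >= p) {
    warning(sprintf(
      "JL dimension %d >= input dimension %d; passing data through unchanged",
      k, p))
    oth <- if (is.null(other)) NULL else as_feature_matrix(other)
    return(list(train = Xtr, other = oth, n_components = as.integer(p)))
  }
  R <- with_seed(seed, matrix(stats::rnorm(p * k, sd = 1 / sqrt(k)), p, k))
  oth <- if (is.null(other)) NULL else as_feature_matrix(other) %*% R
  list(train = Xtr %*% R, other = oth, n_components = as.integer(k))
}
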