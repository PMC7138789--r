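# Shared fixtures, all built in code.

# Two well-separated Gaussian blobs in `dim` dimensions.
make_blobs <- function(n_per_class = 30, dim = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * dim), ncol = dim),
             matrix(rnorm(n_per_class * dim, mean = sep), ncol = dim))
  y <- rep(c(0L, 1L), each = n_per_class)
  ord <- sample(length(y))
  list(X = X[ord, , drop = FALSE], y = y[ord])
}

# Exactly rank-k data: n x p with k latent factors and no noise.
make_rank_k <- function(n = 100, p = 40, k = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n) %*% matrix(rnorm(k * p), k)
}

# Independent AUC oracle: fraction of concordant positive-negative pairs,
# ties counted one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A small trained SAE shared by tests that only need *some* valid encoder.
cached_sae <- local({
  enc <- NULL
  function() {
    if (is.null(enc)) {
      X <- make_rank_k(60, 30, 2, seed = 5)
      arch <- ae_architecture("SAE", input_dim = 30, latent_dim = 4)
      enc <<- train_autoencoder(arch, X[1:45, ], X[46:60, ], seed = 1,
                                max_epochs = 120)
    }
    enc
  }
})
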