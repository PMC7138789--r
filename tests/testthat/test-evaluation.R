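test_that("the 64/16/20 split is exact on balanced data", {
  y <- rep(c(0L, 1L), each = 50)
  sp <- stratified_split(y, seed = 1)
  expect_length(sp$test_idx, 20L)
  expect_length(sp$validation_idx, 16L)
  expect_length(sp$train_idx, 64L)
  all_idx <- c(sp$train_idx, sp$validation_idx, sp$test_idx)
  expect_identical(sort(all_idx), 1:100)

  # class proportions within one sample of proportional in every part
  for (part in list(sp$train_idx, sp$validation_idx, sp$test_idx)) {
    n1 <- sum(y[part])
    expect_lte(abs(n1 - length(part) * 0.5), 1)
  }
})

test_that("stratified rounding matches the per-class oracle on skewed data", {
  # the 85-control / 25-patient shape: round(85*0.2)=17, round(25*0.2)=5
  y <- c(rep(0L, 85), rep(1L, 25))
  sp <- stratified_split(y, seed = 2)
  expect_length(sp$test_idx, 22L)
  expect_equal(sum(y[sp$test_idx] == 0L), 17L)
  expect_equal(sum(y[sp$test_idx] == 1L), 5L)
  # validation: round(0.2*68)=14 controls, round(0.2*20)=4 patients
  expect_equal(sum(y[sp$validation_idx] == 0L), 14L)
  expect_equal(sum(y[sp$validation_idx] == 1L), 4L)

  expect_identical(stratified_split(y, seed = 2), sp)
  sp3 <- stratified_split(y, seed = 3)
  expect_false(identical(sp3$test_idx, sp$test_idx))

  expect_error(stratified_split(c(rep(0L, 30), 1L, 1L, 1L, 1L), seed = 1),
               "at least 5")
})

svm_small_grid <- function() {
  lapply(c(0.1, 1, 10), function(C)
    classifier_spec("SVM", kernel = "linear", C = C))
}

test_that("run_once keeps test rows away from every fitting stage", {
  d <- generate_synthetic(synthetic_spec(120, 60, latent_dim = 4,
                                         effect_size = 2, kind = "abundance",
                                         seed = 30))
  for (reducer in c("none", "PCA", "RP", "SAE")) {
    arch <- if (reducer == "SAE") {
      ae_architecture("SAE", 60, latent_dim = 8)
    }
    cfg <- run_config(reducer = reducer, classifier = "SVM",
                      reducer_architecture = arch, n_repeats = 1,
                      base_seed = 0, classifier_grid = svm_small_grid(),
                      ae_options = list(max_epochs = 30))
    tr <- new.env()
    if (reducer == "RP") {
      # at this width the JL dimension exceeds p and RP passes data through
      expect_warning(run_once(d$profiles, d$labels, cfg, seed = 4,
                              .trace = tr),
                     "passing data through unchanged")
    } else {
      run_once(d$profiles, d$labels, cfg, seed = 4, .trace = tr)
    }
    expect_length(intersect(tr$reducer_rows, tr$split$test_idx), 0L)
    expect_length(intersect(tr$cv_rows, tr$split$test_idx), 0L)
    expect_setequal(tr$cv_rows, setdiff(seq_len(120), tr$split$test_idx))
  }
})

test_that("mutating test rows does not change the trained reducer", {
  d <- generate_synthetic(synthetic_spec(80, 40, latent_dim = 4,
                                         effect_size = 2, kind = "abundance",
                                         seed = 31))
  X <- unclass(d$profiles)
  sp <- stratified_split(d$labels, seed = 6)
  arch <- ae_architecture("SAE", 40, latent_dim = 4)
  e1 <- train_autoencoder(arch, X[sp$train_idx, ], X[sp$validation_idx, ],
                          seed = 6, max_epochs = 30)
  X2 <- X
  X2[sp$test_idx, ] <- matrix(runif(length(sp$test_idx) * 40),
                              length(sp$test_idx))
  e2 <- train_autoencoder(arch, X2[sp$train_idx, ], X2[sp$validation_idx, ],
                          seed = 6, max_epochs = 30)
  expect_identical(e1$enc_layers, e2$enc_layers)
})

test_that("a strong planted signal yields high test AUC without reduction", {
  d <- generate_synthetic(synthetic_spec(200, 300, latent_dim = 8,
                                         effect_size = 3, kind = "marker",
                                         seed = 32))
  cfg <- run_config(reducer = "none", classifier = "SVM", n_repeats = 1,
                    base_seed = 0)
  r <- run_once(d$profiles, d$labels, cfg, seed = 1)
  expect_gte(r$auc, 0.9)
})

test_that("an SAE representation preserves the planted structure", {
  d <- generate_synthetic(synthetic_spec(150, 200, latent_dim = 6,
                                         effect_size = 3, kind = "marker",
                                         seed = 33))
  cfg <- run_config(reducer = "SAE", classifier = "SVM",
                    reducer_architecture = ae_architecture("SAE", 200,
                                                           latent_dim = 16),
                    n_repeats = 1, base_seed = 0,
                    ae_options = list(max_epochs = 150))
  r <- run_once(d$profiles, d$labels, cfg, seed = 1)
  expect_gte(r$auc, 0.85)
})

test_that("repeat_evaluation aggregates per-seed runs exactly", {
  d <- generate_synthetic(synthetic_spec(100, 50, latent_dim = 4,
                                         effect_size = 2, kind = "abundance",
                                         seed = 34))
  cfg <- run_config(reducer = "none", classifier = "SVM", n_repeats = 3,
                    base_seed = 10, classifier_grid = svm_small_grid())
  res <- repeat_evaluation(d$profiles, d$labels, cfg)
  expect_equal(nrow(res$per_seed), 3L)
  expect_identical(res$per_seed$seed, 10:12)
  expect_equal(res$mean_auc, mean(res$per_seed$auc), tolerance = 1e-12)
  expect_equal(res$mean_auprc, mean(res$per_seed$auprc), tolerance = 1e-12)

  # n_repeats = 1 degenerates to the single run
  cfg1 <- run_config(reducer = "none", classifier = "SVM", n_repeats = 1,
                     base_seed = 10, classifier_grid = svm_small_grid())
  res1 <- repeat_evaluation(d$profiles, d$labels, cfg1)
  expect_equal(res1$mean_auc, res1$per_seed$auc[1])
  expect_equal(res1$per_seed$auc[1], res$per_seed$auc[1])

  # identical inputs reproduce the result exactly
  res_again <- repeat_evaluation(d$profiles, d$labels, cfg)
  expect_identical(res_again$per_seed, res$per_seed)
})

test_that("results are written as a table plus a JSON twin", {
  d <- generate_synthetic(synthetic_spec(80, 30, latent_dim = 4,
                                         effect_size = 2, kind = "abundance",
                                         seed = 35))
  cfg <- run_config(reducer = "PCA", classifier = "SVM", n_repeats = 2,
                    base_seed = 0, classifier_grid = svm_small_grid())
  res <- repeat_evaluation(d$profiles, d$labels, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3L)  # 2 seeds + summary row
  expect_equal(tab$auc[3], res$mean_auc, tolerance = 1e-12)
  js <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(js$mean_auc, res$mean_auc, tolerance = 1e-12)
  expect_equal(nrow(js$per_seed), 2L)
})

test_that("run_config validates reducer/architecture pairing", {
  expect_error(run_config(reducer = "SAE", classifier = "RF"),
               "requires reducer_architecture")
  expect_error(run_config(reducer = "none", classifier = "RF",
                          reducer_architecture =
                            ae_architecture("SAE", 10, latent_dim = 4)),
               "only meaningful")
  expect_error(run_config(reducer = "DAE", classifier = "RF",
                          reducer_architecture =
                            ae_architecture("SAE", 10, latent_dim = 4)),
               "does not match")
})
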