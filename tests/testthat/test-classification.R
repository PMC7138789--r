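test_that("classifier grids have the documented cardinalities", {
  svm_grid <- enumerate_classifier_grid("SVM")
  rf_grid <- enumerate_classifier_grid("RF")
  mlp_grid <- enumerate_classifier_grid("MLP")
  expect_length(svm_grid, 60L)
  expect_length(rf_grid, 100L)
  expect_length(mlp_grid, 120L)

  kernels <- vapply(svm_grid, function(s) s$hyper_parameters$kernel, "")
  expect_equal(sum(kernels == "linear"), 6L)
  expect_equal(sum(kernels == "rbf"), 54L)
  gammas <- unique(vapply(svm_grid[kernels == "rbf"],
                          function(s) s$hyper_parameters$gamma, numeric(1)))
  expect_equal(sort(gammas), 2^seq(-13, 3, by = 2))
  Cs <- unique(vapply(svm_grid, function(s) s$hyper_parameters$C, numeric(1)))
  expect_equal(sort(Cs), 2^seq(-5, 5, by = 2))

  expect_setequal(vapply(rf_grid, function(s) s$hyper_parameters$n_estimators,
                         integer(1)), c(100L, 300L, 500L, 700L, 900L))
  expect_length(unique(vapply(mlp_grid, function(s)
    paste(s$hyper_parameters, collapse = "/"), "")), 120L)
})

test_that("MLP hidden widths halve and never fall below one unit", {
  expect_identical(mlp_layer_schedule(100, 3), c(100L, 50L, 25L))
  expect_identical(mlp_layer_schedule(10, 1), 10L)
  expect_identical(mlp_layer_schedule(10, 3), c(10L, 5L, 2L))
  expect_error(mlp_layer_schedule(1, 2), class = "microembed_config_error")
  # every grid point has a valid schedule
  for (s in enumerate_classifier_grid("MLP")) {
    w <- mlp_layer_schedule(s$hyper_parameters$first_layer_units,
                            s$hyper_parameters$n_hidden_layers)
    expect_true(all(w >= 1L))
  }
})

test_that("pipeline AUC equals the pairwise-concordance oracle", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  # a printed toy case, checked by hand: pairs (pos, neg) concordant
  # 7 of 9 with one tie -> (7 + 0.5) / 9... enumerated by the oracle
  s <- c(0.2, 0.8, 0.4, 0.4, 0.9, 0.1)
  y <- c(0, 1, 1, 0, 1, 0)
  expect_equal(auc_score(s, y), pairwise_auc(s, y))
  expect_equal(auc_score(s, y), 8.5 / 9)

  set.seed(10)
  for (i in 1:300) {
    n <- sample(6:40, 1)
    y <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(auc_score(sc, y), pairwise_auc(sc, y), tolerance = 1e-12)
  }

  set.seed(11)
  for (i in 1:10) {
    y <- c(0L, 1L, rbinom(28, 1, 0.4))
    sc <- round(rnorm(30), 1)
    expect_equal(auc_score(sc, y),
                 as.numeric(pROC::auc(y, sc, quiet = TRUE,
                                      direction = "<")),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC behaves on perfect, null and degenerate rankings", {
  expect_equal(auprc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # with scores independent of labels, AUPRC ~ prevalence
  set.seed(12)
  y <- rbinom(4000, 1, 0.3)
  expect_lt(abs(auprc_score(rnorm(4000), y) - 0.3), 0.05)
  # all-tied scores give precision = prevalence at full recall
  expect_equal(auprc_score(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.3)
})

test_that("cross-validated selection finds a separating model on blobs", {
  b <- make_blobs(25, dim = 2, sep = 6, seed = 13)
  sel <- cross_validate_select(b$X, b$y, "SVM", seed = 1)
  expect_s3_class(sel, "cv_selection")
  expect_equal(sel$mean_accuracy, 1.0)
  expect_equal(sel$mean_accuracy, mean(sel$per_fold_accuracy))
  expect_identical(sel$grid_size, 60L)
  expect_length(sel$per_fold_accuracy, 5L)
})

test_that("per-fold accuracies are reproducible by manual refitting", {
  b <- make_blobs(20, dim = 3, sep = 1.5, seed = 14)
  grid <- enumerate_classifier_grid("SVM")[c(2, 10, 40)]
  sel <- cross_validate_select(b$X, b$y, "SVM", seed = 3, grid = grid)
  best_gi <- which(vapply(grid, function(g) identical(g, sel$best_spec),
                          logical(1)))[1]
  # rebuild fold 1 of the winning spec from scratch
  folds <- sel$folds
  tr <- folds != 1L
  model <- microembed:::fit_classifier(sel$best_spec,
                                       b$X[tr, , drop = FALSE], b$y[tr],
                                       seed = 3)
  acc <- accuracy_score(model$predict_scores(b$X[!tr, , drop = FALSE]),
                        b$y[!tr], model$threshold)
  expect_equal(acc, sel$per_fold_accuracy[1])
})

test_that("selection errors when a class is too small to stratify", {
  X <- matrix(rnorm(40), 8)
  expect_error(cross_validate_select(X, c(1, 0, 0, 0, 0, 0, 0, 0), "SVM"),
               "at least 5")
})

test_that("final fit scores held-out data for all three algorithms", {
  b <- make_blobs(30, dim = 4, sep = 3, seed = 15)
  te <- make_blobs(15, dim = 4, sep = 3, seed = 16)
  specs <- list(
    classifier_spec("SVM", kernel = "rbf", C = 2, gamma = 0.125),
    classifier_spec("RF", n_estimators = 100, min_samples_leaf = 1,
                    criterion = "gini", max_features = "sqrt"),
    classifier_spec("MLP", n_hidden_layers = 2, epochs = 200,
                    first_layer_units = 30, dropout = 0.1))
  for (spec in specs) {
    sc <- fit_and_score(b$X, b$y, te$X, te$y, spec, seed = 1)
    expect_gte(sc$auc, 0.95)
    expect_gte(sc$auprc, 0.9)
    expect_gte(sc$accuracy, 0.9)
    expect_length(sc$scores, 30L)
  }
  # RF fits are seeded: repeated calls agree exactly
  sc1 <- fit_and_score(b$X, b$y, te$X, te$y, specs[[2]], seed = 5)
  sc2 <- fit_and_score(b$X, b$y, te$X, te$y, specs[[2]], seed = 5)
  expect_identical(sc1$scores, sc2$scores)
})

test_that("single-class test labels raise an AUC-undefined error", {
  b <- make_blobs(10, dim = 2, seed = 17)
  spec <- classifier_spec("SVM", kernel = "linear", C = 1)
  expect_error(fit_and_score(b$X, b$y, b$X[1:4, ], c(1, 1, 1, 1), spec),
               class = "microembed_single_class_error")
})

test_that("pure-noise features score near chance across repetitions", {
  set.seed(18)
  grid <- enumerate_classifier_grid("SVM")
  aucs <- vapply(1:20, function(r) {
    X <- matrix(rnorm(70 * 10), 70)
    y <- rep(c(0L, 1L), length.out = 70)
    sel <- cross_validate_select(X[1:50, ], y[1:50], "SVM", seed = r,
                                 grid = grid)
    fit_and_score(X[1:50, ], y[1:50], X[51:70, ], y[51:70], sel$best_spec,
                  seed = r)$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
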