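#' Classifier hyper-parameter specification
#'
#' A single point of a classifier's search grid.
#'
#' @param algorithm `"SVM"`, `"RF"` or `"MLP"`.
#' @param ... Algorithm-specific hyper-parameters. SVM: `kernel`
#'   (`"linear"`/`"rbf"`), `C`, and `gamma` (rbf only). RF: `n_estimators`,
#'   `min_samples_leaf`, `criterion` (`"gini"`/`"hellinger"`),
#'   `max_features` (`"sqrt"`/`"log2"`). MLP: `n_hidden_layers`, `epochs`,
#'   `first_layer_units`, `dropout`.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("SVM", "RF", "MLP"), ...) {
  algorithm <- match.arg(algorithm)
  hp <- list(...)
  switch(algorithm,
    SVM = {
      if (!hp$kernel %in% c("linear", "rbf")) me_stop("unknown SVM kernel")
      if (!is.numeric(hp$C) || hp$C <= 0) me_stop("C must be > 0")
      if (hp$kernel == "rbf" && (is.null(hp$gamma) || hp$gamma <= 0)) {
        me_stop("rbf kernel requires gamma > 0")
      }
      if (hp$kernel == "linear") hp$gamma <- NULL
    },
    RF = {
      if (!hp$criterion %in% c("gini", "hellinger")) {
        me_stop("unknown RF split criterion")
      }
      if (!hp$max_features %in% c("sqrt", "log2")) {
        me_stop("unknown RF max_features rule")
      }
      stopifnot(is_count(hp$n_estimators), is_count(hp$min_samples_leaf))
    },
    MLP = {
      stopifnot(is_count(hp$n_hidden_layers), is_count(hp$epochs),
                is_count(hp$first_layer_units))
      if (!is.numeric(hp$dropout) || hp$dropout < 0 || hp$dropout >= 1) {
        me_stop("dropout must lie in [0, 1)")
      }
      # fails if any hidden width would fall below 1
      mlp_layer_schedule(hp$first_layer_units, hp$n_hidden_layers)
    })
  structure(list(algorithm = algorithm, hyper_parameters = hp),
            class = "classifier_spec")
}

#' @export
format.classifier_spec <- function(x, ...) {
  hp <- x$hyper_parameters
  paste0(x$algorithm, "(",
         paste(names(hp), vapply(hp, format, ""), sep = "=", collapse = ","),
         ")")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", format(x), "\n")
  invisible(x)
}

#' Enumerate a classifier's hyper-parameter grid
#'
#' Fixed-order default grids. SVM: a linear kernel crossed with
#' `C = 2^{-5, -3, ..., 5}` (6 points) plus an RBF kernel crossed with the
#' same `C` and `gamma = 2^{-13, -11, ..., 3}` (9 values), 60 combinations
#' in total. RF: trees in \{100, 300, 500, 700, 900\} x minimum leaf size
#' 1..5 x split criterion \{gini, hellinger\} x `max_features`
#' \{sqrt, log2\} = 100. MLP: hidden layers \{1, 2, 3\} x epochs
#' \{30, 50, 100, 200, 300\} x first-layer units \{10, 30, 50, 100\} x
#' dropout \{0.1, 0.3\} = 120.
#'
#' @param algorithm `"SVM"`, `"RF"` or `"MLP"`.
#' @return List of [classifier_spec()] objects; ties in cross-validated
#'   selection are broken by this enumeration order.
#' @export
enumerate_classifier_grid <- function(algorithm = c("SVM", "RF", "MLP")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    SVM = {
      Cs <- 2^seq(-5, 5, by = 2)
      gammas <- 2^seq(-13, 3, by = 2)
      linear <- lapply(Cs, function(C)
        classifier_spec("SVM", kernel = "linear", C = C))
      rbf_grid <- expand.grid(gamma = gammas, C = Cs)
      rbf <- lapply(seq_len(nrow(rbf_grid)), function(i)
        classifier_spec("SVM", kernel = "rbf", C = rbf_grid$C[i],
                        gamma = rbf_grid$gamma[i]))
      c(linear, rbf)
    },
    RF = {
      g <- expand.grid(max_features = c("sqrt", "log2"),
                       criterion = c("gini", "hellinger"),
                       min_samples_leaf = 1:5,
                       n_estimators = c(100L, 300L, 500L, 700L, 900L),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        classifier_spec("RF", n_estimators = g$n_estimators[i],
                        min_samples_leaf = g$min_samples_leaf[i],
                        criterion = g$criterion[i],
                        max_features = g$max_features[i]))
    },
    MLP = {
      g <- expand.grid(dropout = c(0.1, 0.3),
                       first_layer_units = c(10L, 30L, 50L, 100L),
                       epochs = c(30L, 50L, 100L, 200L, 300L),
                       n_hidden_layers = 1:3)
      lapply(seq_len(nrow(g)), function(i)
        classifier_spec("MLP", n_hidden_layers = g$n_hidden_layers[i],
                        epochs = g$epochs[i],
                        first_layer_units = g$first_layer_units[i],
                        dropout = g$dropout[i]))
    })
}

#' Hidden-layer width schedule of the MLP classifier
#'
#' Each hidden layer after the first has half the units of the preceding
#' one (floored). A single sigmoid output unit is appended downstream.
#'
#' @param first_layer_units Units in the first hidden layer.
#' @param n_hidden_layers Number of hidden layers.
#' @return Integer vector of widths, all >= 1.
#' @examples
#' mlp_layer_schedule(100, 3) # 100 50 25
#' @export
mlp_layer_schedule <- function(first_layer_units, n_hidden_layers) {
  if (!is_count(first_layer_units)) me_stop("first_layer_units must be >= 1")
  if (!is_count(n_hidden_layers)) me_stop("n_hidden_layers must be >= 1")
  widths <- first_layer_units %/% 2^(seq_len(n_hidden_layers) - 1L)
  if (any(widths < 1L)) {
    me_stop("hidden layer width falls below 1 unit",
            class = "microembed_config_error")
  }
  as.integer(widths)
}

# ---- backends --------------------------------------------------------------

# Fit one classifier and return a closure producing continuous scores
# (larger = more likely patient) plus the threshold at which accuracy is
# evaluated (0 for margins, 0.5 for probabilities).
fit_classifier <- function(spec, X, y, seed = 0L) {
  y <- check_binary_labels(y)
  hp <- spec$hyper_parameters
  switch(spec$algorithm,
    SVM = {
      yf <- factor(y, levels = c(0L, 1L))
      fit <- with_seed(seed, e1071::svm(
        x = X, y = yf,
        kernel = if (hp$kernel == "rbf") "radial" else "linear",
        cost = hp$C, gamma = hp$gamma %||% 1 / ncol(X), scale = FALSE))
      list(threshold = 0, predict_scores = function(newX) {
        pr <- stats::predict(fit, newX, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        # e1071 orients the margin towards the first factor level it saw;
        # flip so positive margins mean the patient class
        if (colnames(dv)[1L] == "0/1") -drop(dv) else drop(dv)
      })
    },
    RF = {
      mtry <- switch(hp$max_features,
                     sqrt = max(1L, floor(sqrt(ncol(X)))),
                     log2 = max(1L, floor(log2(ncol(X)))))
      fit <- ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)),
        num.trees = hp$n_estimators, mtry = mtry,
        min.bucket = hp$min_samples_leaf,
        splitrule = hp$criterion, probability = TRUE,
        num.threads = getOption("microembed.threads", 1L),
        seed = seed, oob.error = FALSE)
      list(threshold = 0.5, predict_scores = function(newX) {
        p <- stats::predict(fit, data = as.data.frame(newX),
                            num.threads =
                              getOption("microembed.threads", 1L))$predictions
        unname(p[, "1"])
      })
    },
    MLP = {
      fit <- fit_mlp(X, y, hp, seed = seed)
      list(threshold = 0.5, predict_scores = function(newX) {
        drop(sigmoid(net_forward(fit, as_feature_matrix(newX))$out))
      })
    })
}

# MLP classifier: ReLU hidden layers on the halving schedule, dropout after
# each hidden layer, single logistic output, binary cross-entropy, Adam,
# mini-batches of 32, a fixed number of epochs (an explicit grid axis).
fit_mlp <- function(X, y, hp, seed = 0L, batch_size = 32L, lr = 1e-3) {
  widths <- mlp_layer_schedule(hp$first_layer_units, hp$n_hidden_layers)
  dims <- c(ncol(X), widths)
  with_seed(seed, {
    net <- list()
    for (i in seq_along(widths)) {
      net <- c(net, list(nn_dense(dims[i], dims[i + 1L], "relu"),
                         nn_dropout(hp$dropout)))
    }
    net <- c(net, list(nn_dense(widths[length(widths)], 1L, "linear")))
    t <- 0L
    for (epoch in seq_len(hp$epochs)) {
      for (idx in batch_blocks(nrow(X), batch_size)) {
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- net_forward(net, Xb, training = TRUE)
        p <- sigmoid(drop(fw$out))
        dZ <- matrix((p - yb) / length(yb), ncol = 1L)
        bw <- net_backward(net, fw$caches, dZ)
        t <- t + 1L
        net <- net_update(net, bw$grads, t, lr)
      }
    }
    net
  })
}

# ---- selection and scoring -------------------------------------------------

#' Select classifier hyper-parameters by stratified 5-fold cross-validation
#'
#' For every grid point, trains on four folds and scores classification
#' accuracy on the held-out fold, averaging over the five folds; the spec
#' with the highest mean accuracy wins, ties broken by enumeration order
#' (first wins). Folds are stratified by class and fully determined by
#' `seed`. Only the supplied rows are ever touched.
#'
#' @param features Numeric feature matrix (raw or encoded), samples in rows.
#' @param labels 0/1 label vector aligned with the rows.
#' @param algorithm `"SVM"`, `"RF"` or `"MLP"`.
#' @param seed Integer seed for fold assignment and classifier fitting.
#' @param grid Optional list of [classifier_spec()] to search instead of
#'   the default [enumerate_classifier_grid()] grid.
#' @param n_folds Number of cross-validation folds.
#' @return An object of class `cv_selection`: `best_spec`,
#'   `mean_accuracy`, `per_fold_accuracy` (for the winner), `grid_size`,
#'   and the full `grid_mean_accuracy` vector.
#' @export
cross_validate_select <- function(features, labels,
                                  algorithm = c("SVM", "RF", "MLP"),
                                  seed = 0L, grid = NULL, n_folds = 5L) {
  algorithm <- match.arg(algorithm)
  X <- as_feature_matrix(features)
  y <- check_binary_labels(labels)
  if (nrow(X) != length(y)) me_stop("features and labels are not aligned")
  if (min(table(factor(y, levels = 0:1))) < n_folds) {
    me_stop("each class needs at least ", n_folds,
            " samples for stratified ", n_folds, "-fold cross-validation")
  }
  grid <- grid %||% enumerate_classifier_grid(algorithm)
  folds <- stratified_folds(y, n_folds, seed)
  acc <- matrix(NA_real_, length(grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    cache <- new.env(parent = emptyenv())
    for (gi in seq_along(grid)) {
      # distinct grid points can resolve to identical backend fits (e.g.
      # sqrt and log2 give the same mtry at some widths); reuse those
      key <- resolved_key(grid[[gi]], ncol(X))
      if (is.null(cache[[key]])) {
        model <- fit_classifier(grid[[gi]], X[tr, , drop = FALSE], y[tr],
                                seed = seed)
        sc <- model$predict_scores(X[!tr, , drop = FALSE])
        cache[[key]] <- accuracy_score(sc, y[!tr], model$threshold)
      }
      acc[gi, f] <- cache[[key]]
    }
  }
  means <- rowMeans(acc)
  best <- which.max(means)  # first maximum wins
  structure(list(best_spec = grid[[best]], mean_accuracy = means[best],
                 per_fold_accuracy = acc[best, ], grid_size = length(grid),
                 grid_mean_accuracy = means, folds = folds),
            class = "cv_selection")
}

resolved_key <- function(spec, p) {
  hp <- spec$hyper_parameters
  if (spec$algorithm == "RF") {
    mtry <- switch(hp$max_features,
                   sqrt = max(1L, floor(sqrt(p))),
                   log2 = max(1L, floor(log2(p))))
    paste("RF", hp$n_estimators, hp$min_samples_leaf, hp$criterion, mtry,
          sep = "|")
  } else {
    format(spec)
  }
}

# Stratified fold ids: within each class, a seeded shuffle is dealt
# round-robin so fold sizes differ by at most one sample per class.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("<cv_selection> best %s, mean CV accuracy %.3f over %d specs\n",
              format(x$best_spec), x$mean_accuracy, x$grid_size))
  invisible(x)
}

#' Fit a final classifier and score it on held-out data
#'
#' Fits `spec` on all training rows and evaluates on the test rows:
#' ROC AUC, precision-recall AUC, and accuracy at the natural threshold
#' (0.5 on probabilities, 0 on SVM margins).
#'
#' @param train_features,train_labels Training data (row-aligned).
#' @param test_features,test_labels Held-out data.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for the fit.
#' @return List with `auc`, `auprc`, `accuracy` and the continuous test
#'   `scores`.
#' @export
fit_and_score <- function(train_features, train_labels, test_features,
                          test_labels, spec, seed = 0L) {
  stopifnot(inherits(spec, "classifier_spec"))
  ytr <- check_binary_labels(train_labels)
  yte <- check_binary_labels(test_labels)
  if (length(unique(yte)) < 2L) {
    me_stop("test labels contain a single class; AUC is undefined",
            class = "microembed_single_class_error")
  }
  model <- fit_classifier(spec, as_feature_matrix(train_features), ytr,
                          seed = seed)
  scores <- model$predict_scores(as_feature_matrix(test_features))
  list(auc = auc_score(scores, yte), auprc = auprc_score(scores, yte),
       accuracy = accuracy_score(scores, yte, model$threshold),
       scores = scores)
}
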