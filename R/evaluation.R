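#' Stratified 64/16/20 train/validation/test split
#'
#' Outer stratified 8:2 split into non-test vs test, followed by an inner
#' stratified 8:2 split of the non-test portion into train vs validation,
#' giving 64% / 16% / 20% overall. Within each class the test count is
#' `round(0.2 * class_n)` (then `round(0.2 * remainder)` for validation),
#' so per-part class proportions deviate from the full-data proportions by
#' at most one sample. Deterministic given `seed`.
#'
#' @param labels 0/1 label vector; each class needs at least 5 samples.
#' @param seed Integer seed.
#' @return An object of class `data_split` with disjoint integer index
#'   vectors `train_idx`, `validation_idx`, `test_idx` covering all
#'   samples, and the `seed`.
#' @export
stratified_split <- function(labels, seed = 0L) {
  y <- check_binary_labels(labels)
  counts <- table(factor(y, levels = 0:1))
  if (min(counts) < 5L) {
    me_stop("each class needs at least 5 samples to stratify the 64/16/20 split")
  }
  train <- validation <- test <- integer(0)
  with_seed(seed, {
    for (cl in 0:1) {
      idx <- which(unname(y) == cl)
      idx <- idx[sample.int(length(idx))]
      n_test <- round(0.2 * length(idx))
      test <- c(test, idx[seq_len(n_test)])
      rest <- idx[-seq_len(n_test)]
      n_val <- round(0.2 * length(rest))
      validation <- c(validation, rest[seq_len(n_val)])
      train <- c(train, rest[-seq_len(n_val)])
    }
  })
  structure(list(train_idx = sort(train), validation_idx = sort(validation),
                 test_idx = sort(test), seed = as.integer(seed)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / validation %d / test %d (seed %d)\n",
              length(x$train_idx), length(x$validation_idx),
              length(x$test_idx), x$seed))
  invisible(x)
}

#' Evaluation run configuration
#'
#' @param reducer Representation to feed the classifier: `"none"` (raw
#'   features), `"PCA"`, `"RP"` (Gaussian random projection), or an
#'   autoencoder family `"SAE"`/`"DAE"`/`"VAE"`/`"CAE"`.
#' @param classifier `"SVM"`, `"RF"` or `"MLP"`.
#' @param reducer_architecture [ae_architecture()]; required iff `reducer`
#'   is an autoencoder family.
#' @param n_repeats Number of repetitions with different partition seeds.
#' @param base_seed First partition seed; repetition `i` uses
#'   `base_seed + i - 1`.
#' @param classifier_grid Optional custom grid (list of
#'   [classifier_spec()]); default is the full
#'   [enumerate_classifier_grid()] grid.
#' @param ae_options Named list forwarded to [train_autoencoder()]
#'   (`batch_size`, `max_epochs`, `patience`, `learning_rate`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(reducer = c("none", "PCA", "RP", "SAE", "DAE", "VAE",
                                   "CAE"),
                       classifier = c("SVM", "RF", "MLP"),
                       reducer_architecture = NULL, n_repeats = 5L,
                       base_seed = 0L, classifier_grid = NULL,
                       ae_options = list()) {
  reducer <- match.arg(reducer)
  classifier <- match.arg(classifier)
  is_ae <- reducer %in% c("SAE", "DAE", "VAE", "CAE")
  if (is_ae) {
    if (is.null(reducer_architecture)) {
      me_stop("reducer ", reducer, " requires reducer_architecture")
    }
    stopifnot(inherits(reducer_architecture, "ae_architecture"))
    if (reducer_architecture$kind != reducer) {
      me_stop("reducer_architecture kind does not match reducer")
    }
  } else if (!is.null(reducer_architecture)) {
    me_stop("reducer_architecture is only meaningful for autoencoder reducers")
  }
  if (!is_count(n_repeats)) me_stop("n_repeats must be a positive integer")
  structure(list(reducer = reducer, classifier = classifier,
                 reducer_architecture = reducer_architecture,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 classifier_grid = classifier_grid,
                 ae_options = ae_options),
            class = "run_config")
}

#' One leakage-free evaluation run
#'
#' Executes, for one partition seed: stratified 64/16/20 split; fit of the
#' reducer on the non-test portion only (autoencoders train on the 64%
#' train part with the 16% validation part driving early stopping; PCA/RP
#' fit on the merged non-test rows; `"none"` passes raw features); encoding
#' of the non-test and test rows; 5-fold cross-validated hyper-parameter
#' selection on the encoded non-test rows; final fit on all of them and
#' scoring on the encoded test rows. Test rows never reach any
#' parameter-fitting step.
#'
#' @param profiles [profile_matrix()] (or plain matrix), samples in rows.
#' @param labels 0/1 labels aligned with rows.
#' @param config A [run_config()].
#' @param seed Partition seed for this run.
#' @param .trace Optional environment; when supplied, the row indices seen
#'   by the reducer fit (`reducer_rows`) and by classifier selection
#'   (`cv_rows`) are recorded there for leakage auditing.
#' @return List with `seed`, `best_spec`, `auc`, `auprc`, `accuracy`,
#'   `cv_mean_accuracy`, and (for autoencoder reducers) the encoder's
#'   `best_epoch`.
#' @export
run_once <- function(profiles, labels, config, seed = 0L, .trace = NULL) {
  stopifnot(inherits(config, "run_config"))
  X <- as_feature_matrix(profiles)
  y <- check_binary_labels(labels)
  if (nrow(X) != length(y)) me_stop("profiles and labels are not aligned")
  split <- stratified_split(y, seed)
  nontest <- c(split$train_idx, split$validation_idx)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      me_stop("[", name, "] ", conditionMessage(e),
              class = class(e)[1L])
    })
  }
  best_epoch <- NA_integer_
  if (config$reducer == "none") {
    Ztr <- X[nontest, , drop = FALSE]
    Zte <- X[split$test_idx, , drop = FALSE]
    reducer_rows <- integer(0)
  } else if (config$reducer %in% c("PCA", "RP")) {
    red <- stage(config$reducer, {
      if (config$reducer == "PCA") {
        pca_reduce(X[nontest, , drop = FALSE],
                   X[split$test_idx, , drop = FALSE])
      } else {
        rp_reduce(X[nontest, , drop = FALSE],
                  X[split$test_idx, , drop = FALSE], seed = seed)
      }
    })
    Ztr <- red$train
    Zte <- red$other
    reducer_rows <- nontest
  } else {
    enc <- stage(config$reducer, do.call(train_autoencoder, c(
      list(arch = config$reducer_architecture,
           train = X[split$train_idx, , drop = FALSE],
           validation = X[split$validation_idx, , drop = FALSE],
           seed = seed),
      config$ae_options)))
    best_epoch <- enc$best_epoch
    Ztr <- stage("encode", encode(enc, X[nontest, , drop = FALSE]))
    Zte <- stage("encode", encode(enc, X[split$test_idx, , drop = FALSE]))
    reducer_rows <- nontest
  }
  if (!is.null(.trace)) {
    .trace$reducer_rows <- reducer_rows
    .trace$cv_rows <- nontest
    .trace$split <- split
  }
  sel <- stage("cross_validate_select",
               cross_validate_select(Ztr, y[nontest], config$classifier,
                                     seed = seed,
                                     grid = config$classifier_grid))
  sc <- stage("fit_and_score",
              fit_and_score(Ztr, y[nontest], Zte, y[split$test_idx],
                            sel$best_spec, seed = seed))
  list(seed = as.integer(seed), best_spec = sel$best_spec, auc = sc$auc,
       auprc = sc$auprc, accuracy = sc$accuracy,
       cv_mean_accuracy = sel$mean_accuracy, best_epoch = best_epoch)
}

#' Repeated evaluation over partition seeds
#'
#' Runs [run_once()] for seeds `base_seed, ..., base_seed + n_repeats - 1`
#' and averages the test metrics across repetitions; the cross-seed mean
#' AUC is the headline comparison statistic.
#'
#' @inheritParams run_once
#' @return An object of class `evaluation_result`: `per_seed` (data frame
#'   with one row per repetition), `mean_auc`, `mean_auprc`,
#'   `mean_accuracy`, and the `config`.
#' @export
repeat_evaluation <- function(profiles, labels, config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- config$base_seed + seq_len(config$n_repeats) - 1L
  runs <- lapply(seeds, function(s) run_once(profiles, labels, config, s))
  per_seed <- data.frame(
    seed = vapply(runs, `[[`, integer(1), "seed"),
    reducer = config$reducer,
    architecture = if (is.null(config$reducer_architecture)) "" else
      format(config$reducer_architecture),
    classifier = config$classifier,
    best_hyper_parameters = vapply(runs, function(r) format(r$best_spec), ""),
    auc = vapply(runs, `[[`, numeric(1), "auc"),
    auprc = vapply(runs, `[[`, numeric(1), "auprc"),
    accuracy = vapply(runs, `[[`, numeric(1), "accuracy"),
    stringsAsFactors = FALSE)
  structure(list(per_seed = per_seed, mean_auc = mean(per_seed$auc),
                 mean_auprc = mean(per_seed$auprc),
                 mean_accuracy = mean(per_seed$accuracy), config = config),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> %s + %s: mean AUC %.3f, mean AUPRC %.3f over %d seeds\n",
    x$per_seed$reducer[1L], x$per_seed$classifier[1L], x$mean_auc,
    x$mean_auprc, nrow(x$per_seed)))
  invisible(x)
}

#' Write an evaluation result to disk
#'
#' Writes a tab-delimited table with one row per seed plus a final summary
#' row of cross-seed means, and a machine-readable JSON twin at
#' `<path>.json`.
#'
#' @param result An `evaluation_result`.
#' @param path Output path for the delimited table.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  tab <- result$per_seed
  summary_row <- tab[1L, ]
  summary_row$seed <- NA_integer_
  summary_row$best_hyper_parameters <- "mean"
  summary_row$auc <- result$mean_auc
  summary_row$auprc <- result$mean_auprc
  summary_row$accuracy <- result$mean_accuracy
  utils::write.table(rbind(tab, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_seed = tab, mean_auc = result$mean_auc,
         mean_auprc = result$mean_auprc,
         mean_accuracy = result$mean_accuracy),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
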