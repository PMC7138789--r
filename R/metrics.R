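#' Area under the ROC curve
#'
#' Computes the exact area under the receiver-operating-characteristic curve
#' for a continuous score vector against binary labels, using the rank
#' (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive sample is scored above a randomly chosen negative sample, with
#' ties counted as one half. This equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric vector of decision values or probabilities; larger
#'   values mean "more likely positive".
#' @param labels Integer/numeric vector of the same length with values in
#'   \{0, 1\} (1 = patient/positive class).
#' @return A single number in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' @export
auc_score <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) {
    me_stop("scores and labels must have the same length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    me_stop("AUC is undefined when only one class is present",
            class = "microembed_single_class_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: thresholds are swept over the distinct score
#' values from high to low and the area is accumulated as
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}, i.e. precision is not interpolated.
#' Preferred over AUC when the classes are strongly imbalanced.
#'
#' @inheritParams auc_score
#' @return A single number in (0, 1\].
#' @export
auprc_score <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) {
    me_stop("scores and labels must have the same length")
  }
  n1 <- sum(labels == 1L)
  if (n1 == 0L) {
    me_stop("AUPRC is undefined without positive samples",
            class = "microembed_single_class_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # Evaluate precision/recall only at the last index of each tied score block.
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification accuracy at a fixed threshold
#'
#' @inheritParams auc_score
#' @param threshold Decision threshold on the scores: 0.5 for
#'   probability-scaled scores, 0 for SVM margins.
#' @return Fraction of correctly classified samples.
#' @export
accuracy_score <- function(scores, labels, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  mean((scores > threshold) == (labels == 1L))
}

# Validate and coerce a 0/1 label vector (factors and numerics accepted).
check_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    me_stop("labels must be a vector of 0 (control) and 1 (patient)")
  }
  stats::setNames(as.integer(labels), names(labels))
}
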