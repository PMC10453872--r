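# Discriminator-as-classifier prediction and the evaluation stack.

#' Classify images with the discriminator head
#'
#' Runs the discriminator, renormalizes the two real-class probabilities
#' (dropping the fake unit), and reports the malignant posterior as the
#' score. The predicted label is malignant exactly when the score is at
#' least 0.5, so labels and scores are threshold-consistent.
#'
#' @param D a [DiscriminatorNet-class].
#' @param images a (64, 64, 3, n) array in \[-1, 1\] or a list of
#'   [ImageTensor-class] objects in \[0, 1\].
#' @return list with `labels` (integer 0/1) and `scores` (malignant
#'   probability in \[0, 1\]).
#' @export
predictLesions <- function(D, images) {
  if (is.list(images)) images <- imagesToBatch(images)
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  probs <- netForward(D, images)
  scores <- real_class_scores(probs)
  list(labels = as.integer(scores >= 0.5), scores = scores)
}

# renormalize the real-class columns of an n x (N+1) head output and return
# the malignant posterior
real_class_scores <- function(probs) {
  probs <- rbind(probs)
  real <- probs[, 1:2, drop = FALSE]
  unname(real[, 2L] / pmax(rowSums(real), 1e-12))
}

canon_labels <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- !x %in% c("benign", "malignant")
    if (any(bad)) stop("unknown label value: ", x[which(bad)[1L]])
    return(as.integer(x == "malignant"))
  }
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("labels must be 0/1 or benign/malignant")
  x
}

#' Confusion matrix of a binary prediction
#'
#' Counts with malignant (target 1) as the positive class. Labels may be
#' 0/1 integers or `"benign"`/`"malignant"` strings.
#'
#' @param labelsTrue,labelsPred equal-length label vectors.
#' @return a [ConfusionMatrix-class].
#' @export
confusion <- function(labelsTrue, labelsPred) {
  yt <- canon_labels(labelsTrue)
  yp <- canon_labels(labelsPred)
  if (length(yt) != length(yp)) stop("label vectors must have equal length")
  ConfusionMatrix(tp = sum(yt == 1L & yp == 1L),
                  tn = sum(yt == 0L & yp == 0L),
                  fp = sum(yt == 0L & yp == 1L),
                  fn = sum(yt == 1L & yp == 0L))
}

safe_ratio <- function(num, den, metric, degenerate) {
  if (den == 0) {
    degenerate$flags <- c(degenerate$flags, metric)
    return(0)
  }
  num / den
}

#' Confusion-matrix-derived classification metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity, F1 and the
#' balanced accuracy score `BAS = (recall + specificity) / 2`, all in
#' percent. A metric whose denominator is zero is reported as 0 and flagged
#' in the `degenerate` slot rather than raising, so batch evaluation stays
#' total.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return a [MetricsReport-class] (without ROC fields; see [rocAuc()]).
#' @examples
#' classificationMetrics(ConfusionMatrix(tp = 3, tn = 2, fp = 2, fn = 1))
#' @export
classificationMetrics <- function(cm) {
  methods::validObject(cm)
  n <- cm@tp + cm@tn + cm@fp + cm@fn
  if (n == 0L) stop("empty confusion matrix")
  deg <- new.env()
  deg$flags <- character(0)
  accuracy <- (cm@tp + cm@tn) / n
  precision <- safe_ratio(cm@tp, cm@tp + cm@fp, "precision", deg)
  recall <- safe_ratio(cm@tp, cm@tp + cm@fn, "recall", deg)
  specificity <- safe_ratio(cm@tn, cm@tn + cm@fp, "specificity", deg)
  f1 <- safe_ratio(2 * precision * recall, precision + recall, "f1", deg)
  bas <- (recall + specificity) / 2
  new("MetricsReport", accuracy = 100 * accuracy, precision = 100 * precision,
      recall = 100 * recall, specificity = 100 * specificity, f1 = 100 * f1,
      bas = 100 * bas, auc = NA_real_,
      rocPoints = data.frame(fpr = numeric(0), tpr = numeric(0)),
      degenerate = deg$flags)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique scores as thresholds (predict malignant when
#' `score >= t`), tracing true-positive rate against false-positive rate
#' from (0, 0) to (1, 1), and integrates by the trapezoidal rule. Tied
#' scores move along a diagonal segment, which is equivalent to counting
#' tied (positive, negative) pairs 1/2 in the pairwise formulation.
#'
#' @param labelsTrue 0/1 (or benign/malignant) true labels; both classes
#'   must be present.
#' @param scores malignancy scores in \[0, 1\].
#' @return list with `rocPoints` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
rocAuc <- function(labelsTrue, scores) {
  yt <- canon_labels(labelsTrue)
  if (length(yt) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  nPos <- sum(yt == 1L)
  nNeg <- sum(yt == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present to trace a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]
  ss <- scores[ord]
  # cumulative counts at each distinct threshold
  keep <- c(diff(ss) != 0, TRUE)
  tpr <- c(0, cumsum(ys == 1L)[keep] / nPos)
  fpr <- c(0, cumsum(ys == 0L)[keep] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(rocPoints = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a discriminator on a labeled image set
#'
#' Convenience wrapper: predict, tabulate the confusion matrix, compute the
#' metric panel and the ROC/AUC.
#'
#' @param D a [DiscriminatorNet-class].
#' @param images image batch (array or list of [ImageTensor-class]).
#' @param labelsTrue true targets (0/1 or benign/malignant).
#' @return a [MetricsReport-class] with ROC fields filled in.
#' @export
evaluateClassifier <- function(D, images, labelsTrue) {
  pred <- predictLesions(D, images)
  rep <- classificationMetrics(confusion(labelsTrue, pred$labels))
  roc <- rocAuc(labelsTrue, pred$scores)
  rep@auc <- roc$auc
  rep@rocPoints <- roc$rocPoints
  rep
}
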