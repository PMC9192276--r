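#' @include constructors.R
NULL

#' Accuracy, specificity and sensitivity from a confusion matrix
#'
#' With A true positives, B true negatives, C false positives and D false
#' negatives:
#' accuracy = (A + B) / (A + B + C + D), specificity = B / (C + B),
#' sensitivity = A / (D + A). Values are fractions in `[0, 1]`; multiply
#' by 100 for the percentage presentation usual in diagnostic studies.
#' An empty denominator raises an error naming the affected metric.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return Named list with `accuracy`, `specificity`, `sensitivity`.
#' @examples
#' confusionMetrics(confusionMatrix(A = 90, B = 80, C = 10, D = 20))
#' @export
confusionMetrics <- function(cm) {
  if (!is(cm, "ConfusionMatrix")) stopf("'cm' must be a ConfusionMatrix")
  A <- as.numeric(cm@A); B <- as.numeric(cm@B)
  C <- as.numeric(cm@C); D <- as.numeric(cm@D)
  if (A + B + C + D == 0)
    stopf("accuracy is undefined: the confusion matrix is empty")
  if (C + B == 0)
    stopf("specificity is undefined: no negative cases (B + C = 0)")
  if (D + A == 0)
    stopf("sensitivity is undefined: no positive cases (A + D = 0)")
  list(
    accuracy = (A + B) / (A + B + C + D),
    specificity = B / (C + B),
    sensitivity = A / (D + A)
  )
}

#' ROC curve and AUC of a score-based classifier
#'
#' Sweeps the decision threshold over the unique score values (descending,
#' preceded by a +Inf sentinel so the curve starts at the origin), using
#' the prediction rule score >= threshold — ties with the threshold are
#' predicted positive. The area under the curve is computed by the
#' trapezoidal rule over (FPR, TPR), which equals the Mann-Whitney
#' concordance probability with ties counted half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary reference labels (0/1, logical, or a two-level
#'   factor) of the same length; both classes must be present.
#' @return A [RocCurve-class].
#' @examples
#' rocCurve(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))@auc   # 0.75
#' @export
rocCurve <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1L)
  scores <- as.numeric(scores)
  if (length(scores) != length(labels))
    stopf("'scores' and 'labels' must have equal length")
  if (anyNA(scores) || anyNA(labels)) stopf("missing values are not allowed")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stopf("labels must contain at least one positive and one negative case")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # cumulative counts at each distinct score (last index of each tie block)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  thresholds <- c(Inf, s[last])
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  new("RocCurve", thresholds = thresholds, fpr = fpr, tpr = tpr,
      auc = min(max(auc, 0), 1))
}
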