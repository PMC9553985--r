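# ROC / precision-recall evaluation

#' ROC curve, AUROC, precision-recall and average precision
#'
#' `rocCurve` returns the empirical ROC points (thresholds swept over the
#' observed scores, descending) and the trapezoid AUROC; `aurocPairs` is the
#' equivalent concordant-pair (Mann-Whitney) statistic with ties counted 1/2
#' — the two agree to numerical precision and are cross-checked in the test
#' suite. `prCurve` returns precision-recall points and the step-integral
#' average precision (AP).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @return `rocCurve`: list with `fpr`, `tpr`, `thresholds`, `auroc`;
#'   `aurocPairs`: a single number; `prCurve`: list with `recall`,
#'   `precision`, `average_precision`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores to single ROC points
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  P <- sum(labels); N <- sum(!labels)
  fpr <- c(0, fp / N); tpr <- c(0, tp / P)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auroc = auroc)
}

#' @rdname rocCurve
#' @export
aurocPairs <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(any(labels), any(!labels))
  r <- rank(scores)
  P <- sum(labels); N <- sum(!labels)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

#' @rdname rocCurve
#' @export
prCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(any(labels))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  # AP: sum of precision at each new true positive / total positives
  ap <- sum(precision[y]) / sum(y)
  list(recall = recall, precision = precision, average_precision = ap)
}
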