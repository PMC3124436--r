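## Confusion counting and the five standard evaluation measures.
## Recall, precision, accuracy and F1 are reported as percentages; MCC on
## its natural [-1, 1] scale.  Any measure with a zero denominator is 0
## by convention.

#' Confusion counts of a prediction track
#'
#' @param pred 0/1 predictions (`NA` = residue not scored).
#' @param truth 0/1 reference labels, same length.
#' @return named integer vector `c(TP, FP, TN, FN)`; residues with `NA`
#'   in either vector are excluded from the tally.
#' @export
confusionCounts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth cover different residue sets", call. = FALSE)
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  c(TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    TN = sum(pred == 0L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L))
}

#' Evaluation measures from confusion counts
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/total, F1 = 2PR/(P+R) (all as percentages), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector
#'   `c(recall, precision, accuracy, f1, mcc)`.
#' @examples
#' computeMetrics(c(TP = 4018, FP = 7824, TN = 24888, FN = 1061))
#' @export
computeMetrics <- function(counts) {
  counts <- as.numeric(counts[c("TP", "FP", "TN", "FN")])
  if (anyNA(counts) || any(counts < 0))
    stop("counts must provide non-negative TP, FP, TN, FN", call. = FALSE)
  tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  recall <- sdiv(tp, tp + fn)
  precision <- sdiv(tp, tp + fp)
  accuracy <- (tp + tn) / total
  f1 <- sdiv(2 * precision * recall, precision + recall)
  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / sqrt(mccDen)
  c(recall = 100 * recall, precision = 100 * precision,
    accuracy = 100 * accuracy, f1 = 100 * f1, mcc = mcc)
}

#' Unweighted average of per-fold metrics
#'
#' Cross-validated performance is the arithmetic mean of the per-fold
#' measures (not the metrics of the pooled counts; the two differ
#' slightly whenever folds are unbalanced).
#'
#' @param perFold list of metric vectors from [computeMetrics()].
#' @return named numeric vector of the same shape.
#' @export
foldAverage <- function(perFold) {
  stopifnot(length(perFold) >= 1)
  Reduce(`+`, perFold) / length(perFold)
}
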