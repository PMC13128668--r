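# Confusion-matrix construction and the six evaluation metrics. The
# positive class is long-lived: TP counts proteins correctly predicted
# long-lived, TN proteins correctly predicted short-lived.

#' Confusion counts for two-class labels
#'
#' @param truth,predicted Equal-length vectors over
#'   `"short_lived"` / `"long_lived"`.
#' @return List with integer `TP`, `TN`, `FP`, `FN` (positive class =
#'   long-lived).
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predictions differ in length")
  }
  known <- c(LABEL_SHORT, LABEL_LONG)
  if (!all(truth %in% known) || !all(predicted %in% known)) {
    stop("labels must be 'short_lived' or 'long_lived'")
  }
  list(TP = sum(truth == LABEL_LONG & predicted == LABEL_LONG),
       TN = sum(truth == LABEL_SHORT & predicted == LABEL_SHORT),
       FP = sum(truth == LABEL_SHORT & predicted == LABEL_LONG),
       FN = sum(truth == LABEL_LONG & predicted == LABEL_SHORT))
}

#' The six evaluation metrics
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value, and the Matthews correlation coefficient, computed exactly from
#' the confusion counts. Any metric whose denominator is zero is reported
#' as 0 and flagged in the `degenerate` attribute (the standard MCC
#' convention for a zero denominator factor).
#'
#' @param counts List with `TP`, `TN`, `FP`, `FN` (total > 0).
#' @return Named numeric vector `ACC`, `SEN`, `SPE`, `PPV`, `NPV`, `MCC`
#'   with a logical attribute `degenerate` naming flagged metrics.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP)
  tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated samples")
  safe <- function(num, den) if (den > 0) num / den else 0
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- c(ACC = (tp + tn) / total,
           SEN = safe(tp, tp + fn),
           SPE = safe(tn, tn + fp),
           PPV = safe(tp, tp + fp),
           NPV = safe(tn, tn + fn),
           MCC = if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0)
  degen <- c(ACC = FALSE, SEN = (tp + fn) == 0, SPE = (tn + fp) == 0,
             PPV = (tp + fp) == 0, NPV = (tn + fn) == 0, MCC = mcc_den == 0)
  attr(out, "degenerate") <- degen
  out
}
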