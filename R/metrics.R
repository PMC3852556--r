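# Confusion counting and the four performance measures Sn, Sp, ACC, MCC.
# Positives are coding (+1), negatives noncoding (-1).

#' Confusion counts for -1/+1 labels
#'
#' @param truth,predicted equal-length vectors over \{-1, +1\};
#'   positives = coding = +1.
#' @return object of class `confusion_counts`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (any(!truth %in% c(-1, 1)) || any(!predicted %in% c(-1, 1))) {
    stop("labels must be -1 or +1", call. = FALSE)
  }
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 TN = sum(truth == -1 & predicted == -1),
                 FP = sum(truth == -1 & predicted == 1),
                 FN = sum(truth == 1 & predicted == -1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/n`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.
#' Any zero factor in the MCC denominator gives MCC = 0 by convention;
#' an empty class makes Sn or Sp `NaN` with a warning.
#'
#' @param c a `confusion_counts` (or a list with TP/TN/FP/FN).
#' @return named numeric vector `c(Sn, Sp, ACC, MCC)`.
#' @export
classification_metrics <- function(c) {
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative counts", call. = FALSE)
  n <- tp + tn + fp + fn
  if (n == 0) stop("all-zero confusion counts", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    warning("empty class: Sn or Sp undefined (NaN)", call. = FALSE)
  }
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / n
  denom2 <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  c(Sn = sn, Sp = sp, ACC = acc, MCC = mcc)
}
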