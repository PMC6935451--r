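#' Build a confusion matrix
#'
#' The positive class is "normal" by the convention of this pipeline
#' (`P` = normal breasts, `N` = abnormal), so TPR is sensitivity to the
#' normal class and SPC specificity to the abnormal class.
#'
#' @param truth,pred Vectors of class labels (character or factor).
#' @param positive Label treated as positive.
#' @return Object of class `confusion_matrix`: list with `TP`, `FP`,
#'   `TN`, `FN`, `P`, `N`.
#' @export
confusion_matrix <- function(truth, pred, positive = "normal") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  new_confusion(TP = sum(truth == positive & pred == positive),
                FP = sum(truth != positive & pred == positive),
                TN = sum(truth != positive & pred != positive),
                FN = sum(truth == positive & pred != positive))
}

#' @rdname confusion_matrix
#' @param TP,FP,TN,FN Non-negative counts.
#' @export
new_confusion <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) abort("Validation error: negative confusion counts.")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 P = TP + FN, N = FP + TN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d (P=%d, N=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$P, x$N))
  invisible(x)
}

# Mann-Whitney rank AUC of positive-class scores (midranks for ties).
auc_rank <- function(scores, is_positive) {
  np <- sum(is_positive); nn <- sum(!is_positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification quality indicators
#'
#' Computes the standard confusion-matrix indicators: sensitivity
#' `TPR = TP/P`, precision `PPV = TP/(TP+FP)`, false discovery rate
#' `FDR = FP/(FP+TP)`, `F1 = 2 TP/(2 TP+FP+FN)` and the harmonic mean
#' `HM = 2 TPR PPV/(TPR+PPV)` (identical when both are defined),
#' specificity `SPC = TN/N`, negative predictive value `NPV = TN/(TN+FN)`,
#' accuracy `ACC = (TP+TN)/(TP+FP+TN+FN)`, fall-out `FPR = FP/N`, and the
#' rank-statistic (Mann-Whitney) AUC when per-sample positive-class scores
#' are supplied.  Zero-denominator indicators are reported as `NA`
#' (undefined), never silently 0.
#'
#' @param cm A [confusion_matrix()].
#' @param scores Optional numeric positive-class scores, one per sample.
#' @param truth Optional truth labels aligned with `scores`.
#' @param positive Positive label for `truth`.
#' @return One-row tibble with columns `TPR`, `PPV`, `FDR`, `F1`, `HM`,
#'   `SPC`, `NPV`, `ACC`, `FPR`, `AUC`.
#' @export
classification_metrics <- function(cm, scores = NULL, truth = NULL,
                                   positive = "normal") {
  stopifnot(inherits(cm, "confusion_matrix"))
  div <- function(num, den) if (den > 0) num / den else NA_real_
  TPR <- div(cm$TP, cm$P)
  PPV <- div(cm$TP, cm$TP + cm$FP)
  FDR <- div(cm$FP, cm$FP + cm$TP)
  F1 <- div(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN)
  HM <- if (!is.na(TPR) && !is.na(PPV) && (TPR + PPV) > 0)
    2 * TPR * PPV / (TPR + PPV) else NA_real_
  SPC <- div(cm$TN, cm$N)
  NPV <- div(cm$TN, cm$TN + cm$FN)
  ACC <- div(cm$TP + cm$TN, cm$TP + cm$FP + cm$TN + cm$FN)
  FPR <- div(cm$FP, cm$N)
  AUC <- if (is.null(scores)) NA_real_ else {
    if (is.null(truth)) abort("`truth` is required to compute AUC from scores.")
    auc_rank(scores, as.character(truth) == positive)
  }
  tibble(TPR = TPR, PPV = PPV, FDR = FDR, F1 = F1, HM = HM,
         SPC = SPC, NPV = NPV, ACC = ACC, FPR = FPR, AUC = AUC)
}

#' Zijdenbos Similarity Index of two binary masks
#'
#' `ZSI = 2 |A1 intersect A2| / (|A1| + |A2|)`, identical to the Dice
#' coefficient; symmetric, 1 for identical non-empty masks, 0 for
#' disjoint ones.  Values above 0.75 are conventionally read as excellent
#' agreement between two segmentations.
#'
#' @param a1,a2 Binary masks of equal shape (0/1 or logical matrices).
#' @return Scalar in `[0, 1]`.
#' @export
zsi <- function(a1, a2) {
  a1 <- as_mask(a1, "a1"); a2 <- as_mask(a2, "a2")
  if (!all(dim(a1) == dim(a2)))
    abort("Validation error: masks have different shapes.")
  s <- sum(a1) + sum(a2)
  if (s == 0) abort("Undefined ZSI: both masks are empty.")
  2 * sum(a1 == 1L & a2 == 1L) / s
}
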