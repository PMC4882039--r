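#' Binary confusion counts with lncRNA (NONCODING) as the positive class
#'
#' @param y_true,y_pred Equal-length label vectors over
#'   `{"CODING", "NONCODING"}`.
#' @param positive The positive class label (default `"NONCODING"`:
#'   a true positive is a correctly identified lncRNA, a true negative a
#'   correctly identified mRNA).
#' @return A `confusion_counts` list with integer fields `TP`, `FP`, `TN`,
#'   `FN` summing to the number of evaluated samples.
#' @export
confusion_counts <- function(y_true, y_pred, positive = "NONCODING") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  structure(list(TP = sum(pos_t & pos_p),
                 FP = sum(!pos_t & pos_p),
                 TN = sum(!pos_t & !pos_p),
                 FN = sum(pos_t & !pos_p)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)` (fractions),
#' `ACC = (TP + TN) / total * 100` (percent), and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`. MCC is
#' defined as 0 whenever any factor of its denominator is zero.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metric_set` list with fields `Sn`, `Sp`, `ACC`, `MCC`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total == 0) stop("confusion counts are all zero")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total * 100
  den <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  structure(list(Sn = sn, Sp = sp, ACC = acc, MCC = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn = %.4f  Sp = %.4f  ACC = %.2f%%  MCC = %.4f\n",
              x$Sn, x$Sp, x$ACC, x$MCC))
  if (!is.null(x$AUC)) cat(sprintf("AUC = %.4f\n", x$AUC))
  invisible(x)
}

#' Area under the ROC curve via the rank statistic
#'
#' Computes AUC as the normalized Mann-Whitney statistic with midranks for
#' tied scores: the probability that a randomly chosen positive (NONCODING)
#' transcript receives a higher non-coding score than a randomly chosen
#' negative one, ties counting one half.
#'
#' @param scores Non-coding scores (higher means more likely non-coding).
#' @param y_true True labels; both classes must be present.
#' @param positive The positive class label.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true, positive = "NONCODING") {
  stopifnot(length(scores) == length(y_true))
  pos <- as.character(y_true) == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve points
#'
#' @param scores,y_true,positive As in [roc_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the two trivial endpoints, ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, y_true, positive = "NONCODING") {
  pos <- as.character(y_true) == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1L))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}
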