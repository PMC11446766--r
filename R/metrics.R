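#' Threshold-based classification metrics
#'
#' Computes the confusion matrix at a score threshold together with the
#' panel of threshold-dependent metrics used throughout the package:
#' precision (PRE), sensitivity (SEN), specificity (SPE), accuracy (ACC)
#' and F1.  A sample is predicted positive when its score is greater than
#' or equal to `threshold`.  Ratios with a zero denominator (for example
#' precision when nothing is predicted positive) are reported as `NA`,
#' never coerced to 0.
#'
#' @param y binary labels (0/1 or logical); 1 is the positive class.
#' @param scores numeric scores or probabilities, same length as `y`.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `metrics_panel`: a list with integer counts
#'   `TP`, `FP`, `TN`, `FN` and metrics `PRE`, `SEN`, `SPE`, `ACC`, `F1`.
#' @export
confusion_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  if (length(y) != length(scores)) stopf("y and scores differ in length (%d vs %d)", length(y), length(scores))
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (any(!y %in% c(0L, 1L))) stopf("y must be binary 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  pre <- ratio(tp, tp + fp)
  sen <- ratio(tp, tp + fn)
  spe <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  f1 <- if (!is.na(pre) && !is.na(sen) && (pre + sen) > 0) 2 * pre * sen / (pre + sen) else NA_real_
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 PRE = pre, SEN = sen, SPE = spe, ACC = acc, F1 = f1),
            class = "metrics_panel")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted one
#' half.  Computed from mid-ranks, so it is exact for tied scores and
#' invariant under strictly monotone transforms of the scores.
#'
#' @inheritParams confusion_metrics
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, scores) {
  y <- as.integer(y)
  if (length(y) != length(scores)) stopf("y and scores differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("roc_auc needs both classes present (got %d positives, %d negatives)", n1, n0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: the sum over descending unique score
#' thresholds of precision times the recall increment.  Tied scores enter
#' the curve as a single block.  Trapezoidal interpolation in PR space is
#' deliberately not used (it is optimistic between operating points).
#'
#' @inheritParams confusion_metrics
#' @return average precision in (0, 1\].
#' @export
pr_auc <- function(y, scores) {
  y <- as.integer(y)
  if (length(y) != length(scores)) stopf("y and scores differ in length")
  npos <- sum(y == 1L)
  if (npos == 0L) stopf("pr_auc needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  # block boundaries at unique score values (descending)
  last <- cumsum(table(factor(ss, levels = unique(ss))))  # index of last member per block
  tp <- cumsum(ys)[last]
  n_cum <- as.numeric(last)
  prec <- tp / n_cum
  rec <- tp / npos
  sum(prec * diff(c(0, rec)))
}

#' Stratified k-fold assignment
#'
#' Deterministically (given `seed`) partitions indices into `k` folds such
#' that every fold's class ratio is within one sample of the global ratio:
#' within each class the indices are shuffled and dealt round-robin.
#'
#' @param y binary labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold labels in `1:k`, one per sample.
#' @export
stratified_kfold <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (k < 2) stopf("k must be >= 2")
  tab <- table(y)
  if (any(tab < k)) stopf("class %s has %d members, fewer than k = %d",
                          names(tab)[which.min(tab)], min(tab), k)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Full metrics panel for a scored test set
#'
#' Combines [confusion_metrics()] at a threshold with the ranking metrics
#' [roc_auc()] and [pr_auc()], in the column layout PRE / SEN / SPE / ACC /
#' F1 / ROC-AUC / PR-AUC used for model comparison tables.
#'
#' @inheritParams confusion_metrics
#' @return one-row `data.frame` with the seven metrics plus counts.
#' @export
metrics_panel <- function(y, scores, threshold = 0.5) {
  cm <- confusion_metrics(y, scores, threshold)
  data.frame(PRE = cm$PRE, SEN = cm$SEN, SPE = cm$SPE, ACC = cm$ACC, F1 = cm$F1,
             ROC_AUC = roc_auc(y, scores), PR_AUC = pr_auc(y, scores),
             TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN)
}

#' @export
print.metrics_panel <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  for (m in c("PRE", "SEN", "SPE", "ACC", "F1"))
    cat(sprintf("  %-4s %s\n", m, ifelse(is.na(x[[m]]), "undefined", sprintf("%.4f", x[[m]]))))
  invisible(x)
}
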