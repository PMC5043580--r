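#' Confusion counts at a score cutoff
#'
#' @param scores Numeric scores in \[0, 1\] (or any monotone score).
#' @param labels Class labels; `positive_label` marks the positive class.
#' @param cutoff Scores `>= cutoff` are predicted positive.
#' @param positive_label Label treated as positive.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, cutoff = 0.5, positive_label = "positive") {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pos <- labels == positive_label
  pred <- scores >= cutoff
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 tn = sum(!pred & !pos), fn = sum(!pred & pos)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

.ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' The standard confusion-table ratios: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and
#' false discovery rate `FP/(TP+FP)`. A zero denominator returns `NA`
#' (undefined), never an error; `fdr + ppv = 1` whenever defined.
#'
#' @param c A `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return Proportion in \[0, 1\], or `NA` when undefined.
#' @export
sensitivity <- function(c) .ratio(c$tp, c$tp + c$fn)

#' @rdname sensitivity
#' @export
specificity <- function(c) .ratio(c$tn, c$tn + c$fp)

#' @rdname sensitivity
#' @export
ppv <- function(c) .ratio(c$tp, c$tp + c$fp)

#' @rdname sensitivity
#' @export
fdr <- function(c) .ratio(c$fp, c$tp + c$fp)

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic (average ranks, so ties count one
#' half); the curve is a threshold sweep over the distinct scores whose
#' trapezoidal area equals the same value.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Class labels.
#' @param positive_label Label treated as positive.
#' @return A `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels, positive_label = "positive") {
  pos <- labels == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute ROC")
  r <- rank(scores)  # average ranks handle ties (Mann-Whitney convention)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(tabulate(match(scores[pos], thr), nbins = length(thr)))
  fp <- cumsum(tabulate(match(scores[!pos], thr), nbins = length(thr)))
  structure(list(thresholds = c(Inf, thr),
                 fpr = c(0, fp / n0), tpr = c(0, tp / n1), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Full metric report at a cutoff
#'
#' @inheritParams confusion
#' @return List with confusion counts, sensitivity, specificity, ppv, fdr,
#'   auc and the cutoff used.
#' @export
evaluate_scores <- function(scores, labels, cutoff = 0.5, positive_label = "positive") {
  cc <- confusion(scores, labels, cutoff, positive_label)
  roc <- roc_auc(scores, labels, positive_label)
  list(confusion = cc, sensitivity = sensitivity(cc), specificity = specificity(cc),
       ppv = ppv(cc), fdr = fdr(cc), auc = roc$auc, cutoff = cutoff, roc = roc)
}
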