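#' Confusion counts at a threshold
#'
#' @param labels 0/1 labels.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Positive class is score strictly greater than this.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  list(TP = sum(pred == 1 & labels == 1),
       TN = sum(pred == 0 & labels == 0),
       FP = sum(pred == 1 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with average-rank tie handling,
#' equal to the trapezoidal area under the empirical ROC curve.
#' Returns `NA` with a warning when only one class is present.
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores.
#' @return AUROC in `[0, 1]` or `NA`.
#' @export
auroc_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free summation: thresholds sweep the distinct scores
#' in decreasing order and the area is `sum((R_i - R_{i-1}) * P_i)`
#' over the threshold blocks (tied scores enter together).
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores.
#' @return AUPR in `[0, 1]` or `NA` when no positives exist.
#' @export
aupr_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) {
    warning("AUPR undefined with a single class")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- labels[ord]
  sc <- scores[ord]
  ends <- cumsum(rle(sc)$lengths)
  tp <- cumsum(ys)[ends]
  prec <- tp / ends
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics report
#'
#' Accuracy, precision, recall, F1 and Matthews correlation coefficient
#' from the confusion counts at `threshold`, plus rank-based AUROC and
#' summation AUPR. An MCC with a zero denominator is defined as 0;
#' precision with no predicted positives is 0 by the same convention.
#'
#' @param labels 0/1 labels.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5, strictly greater).
#' @return A `metrics_report` list with auroc, aupr, accuracy,
#'   precision, recall, f1, mcc and the confusion counts.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  cc <- confusion_counts(labels, scores, threshold)
  n <- with(cc, TP + TN + FP + FN)
  acc <- with(cc, (TP + TN) / n)
  prec <- with(cc, if (TP + FP == 0) 0 else TP / (TP + FP))
  rec <- with(cc, if (TP + FN == 0) 0 else TP / (TP + FN))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  mcc_den <- with(cc, sqrt(as.numeric(TP + FN) * (TN + FP) *
                             (TP + FP) * (TN + FN)))
  mcc <- if (mcc_den == 0) 0 else
    with(cc, (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den)
  single_class <- length(unique(labels)) < 2
  if (single_class) warning("rank metrics undefined with a single class")
  structure(list(auroc = if (single_class) NA_real_ else
    auroc_score(labels, scores),
                 aupr = if (single_class) NA_real_ else
    aupr_score(labels, scores),
                 accuracy = acc, precision = prec, recall = rec,
                 f1 = f1, mcc = mcc, counts = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("AUROC %.3f  AUPR %.3f  Acc %.3f  Prec %.3f  ",
                     "Rec %.3f  F1 %.3f  MCC %.3f\n"),
              x$auroc, x$aupr, x$accuracy, x$precision, x$recall,
              x$f1, x$mcc))
  invisible(x)
}

#' Recall stratified by model-confidence bins
#'
#' Splits sites into pLDDT bins (defaults: below 30, 30-50, 50-70,
#' 70-90, above 90) and reports the recall within each bin. Bins are
#' half-open `[lower, upper)` with the top bin closed at 100. Bins
#' without positive sites are reported as `NA`.
#'
#' @param labels 0/1 labels.
#' @param scores Scores.
#' @param plddt Per-site pLDDT values (0-100).
#' @param breaks Bin edges (default `c(0, 30, 50, 70, 90, 100)`).
#' @param threshold Decision threshold.
#' @return Named numeric vector of per-bin recall.
#' @export
stratified_plddt_eval <- function(labels, scores, plddt,
                                  breaks = c(0, 30, 50, 70, 90, 100),
                                  threshold = 0.5) {
  stopifnot(length(labels) == length(scores),
            length(labels) == length(plddt))
  bin <- cut(plddt, breaks, right = FALSE, include.lowest = TRUE,
             labels = paste0("[", breaks[-length(breaks)], ",",
                             breaks[-1], ")"))
  out <- vapply(levels(bin), function(b) {
    i <- which(bin == b & labels == 1)
    if (length(i) == 0) return(NA_real_)
    mean(scores[i] > threshold)
  }, numeric(1))
  names(out) <- levels(bin)
  out
}

#' Spearman correlation between scores and pLDDT
#'
#' Rank correlation with average-rank tie handling; `NA` with a warning
#' when either input is constant.
#'
#' @param scores Predicted probabilities.
#' @param plddt pLDDT values.
#' @return Correlation in `[-1, 1]` or `NA`.
#' @export
spearman_score_plddt <- function(scores, plddt) {
  stopifnot(length(scores) == length(plddt), length(scores) >= 3)
  if (stats::sd(scores) == 0 || stats::sd(plddt) == 0) {
    warning("Spearman correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(rank(scores, ties.method = "average"),
             rank(plddt, ties.method = "average"))
}
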