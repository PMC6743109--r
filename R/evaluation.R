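# Confusion-matrix metrics and ROC/AUC.  The positive class is lncRNA
# (label 0) throughout: TP counts lncRNA predicted as lncRNA.

#' Confusion counts
#'
#' @param truth,predicted integer label vectors in \{0, 1\} of equal
#'   length; lncRNA (0) is the positive class.
#' @return object of class `"confusion_counts"`: list with `TP`, `FN`,
#'   `FP`, `TN` and `n`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted have different lengths")
  }
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  pos <- truth == 0
  ppos <- predicted == 0
  structure(
    list(TP = sum(pos & ppos), FN = sum(pos & !ppos),
         FP = sum(!pos & ppos), TN = sum(!pos & !ppos),
         n = length(truth)),
    class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 `2TP/(2TP+FP+FN)` (the harmonic mean of precision and recall).
#' Zero denominators yield `NA` ("undefined") rather than an error.
#'
#' @param counts a [confusion_counts] object.
#' @return named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
eval_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("no evaluated records")
  with(counts, list(
    accuracy = (TP + TN) / n,
    precision = safe_ratio(TP, TP + FP),
    recall = safe_ratio(TP, TP + FN),
    f1 = safe_ratio(2 * TP, 2 * TP + FP + FN)))
}

#' ROC curve and area under it
#'
#' Threshold sweep over the distinct positive-class scores (descending),
#' giving one (FPR, TPR) point per threshold; the area is the trapezoidal
#' integral.  Tied scores collapse onto one point, which makes the area
#' equal to the concordant-pair (Mann-Whitney) estimator with ties counted
#' one half.
#'
#' @param truth integer labels (0 = lncRNA = positive, 1 = mRNA).
#' @param scores numeric score of being the positive class (e.g. the
#'   predicted lncRNA probability); higher means more lncRNA-like.
#' @return object of class `"roc_result"`: data.frame `points` (columns
#'   `threshold`, `fpr`, `tpr`) and number `auc`.
#' @export
roc_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  n_pos <- sum(truth == 0)
  n_neg <- sum(truth == 1)
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- truth[ord] == 0
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  points <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC =", format(x$auc, digits = 4), "over",
      nrow(x$points) - 1, "thresholds\n")
  invisible(x)
}

#' Assemble an evaluation report for one model on one test set
#'
#' @param truth,predicted integer labels in \{0, 1\}.
#' @param scores optional positive-class (lncRNA) scores for ROC/AUC.
#' @param model_name label used in comparison tables.
#' @return object of class `"eval_report"`: confusion counts, the four
#'   metrics, `auc` (NA without scores) and `model_name`.
#' @export
eval_report <- function(truth, predicted, scores = NULL,
                        model_name = "model") {
  counts <- confusion_counts(truth, predicted)
  m <- eval_metrics(counts)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(truth, scores)$auc
  structure(
    c(list(counts = counts, model_name = model_name, auc = auc,
           n = counts$n, truth = truth), m),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report [%s]: n=%d  acc=%.4f  P=%.4f  R=%.4f  F1=%.4f  AUC=%s\n",
    x$model_name, x$n, x$accuracy, x$precision, x$recall, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an [eval_report].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model_name,
         counts = report$counts[c("TP", "FN", "FP", "TN")],
         accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1, auc = report$auc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
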