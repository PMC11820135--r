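#' Confusion matrix for the binary fist/rest task
#'
#' @param truth,predicted label vectors of equal length with values in
#'   `{"rest", "fist"}`.
#' @return 2x2 integer matrix, rows = truth, columns = prediction, in the
#'   order rest, fist.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  lv <- c("rest", "fist")
  bad <- setdiff(unique(c(truth, predicted)), lv)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m <- table(factor(truth, lv), factor(predicted, lv))
  out <- matrix(as.integer(m), 2, 2,
                dimnames = list(truth = lv, predicted = lv))
  out
}

#' ROC curve from scores
#'
#' One point per distinct threshold (descending), beginning at (0, 0) and
#' ending at (1, 1), with `fist` as the positive class. The trapezoidal
#' area under this curve equals the probability that a random fist score
#' exceeds a random rest score, counting ties as one half.
#'
#' @param scores numeric vector of `P(fist)` (or any monotone score).
#' @param truth labels in `{"rest", "fist"}`; both classes must be present.
#' @return Data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop("`scores` and `truth` lengths differ", call. = FALSE)
  pos <- truth == "fist"
  if (!any(pos) || all(pos))
    stop("ROC requires both classes in `truth`", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(pos); nn <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nn, 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_curve()]; identical (to floating-point
#' tolerance) to pairwise counting with half credit for ties.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  roc <- roc_curve(scores, truth)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Full metrics report
#'
#' Computes the evaluation suite for a binary decoder run: accuracy, F1 for
#' the fist (minority, actionable) class, Cohen's Kappa
#' `(p_o - p_e) / (1 - p_e)` with the chance term from the confusion-matrix
#' marginals, and trapezoidal AUC over the score-threshold ROC.
#'
#' @param truth labels in `{"rest", "fist"}`.
#' @param scores per-epoch `P(fist)`.
#' @param threshold decision threshold turning scores into labels
#'   (`P(fist) >= threshold` predicts fist). Ignored when `predicted` is
#'   given explicitly.
#' @param predicted optional explicit label predictions.
#' @return An object of class `metrics_report` with elements `f1`, `kappa`,
#'   `accuracy`, `auc`, `confusion`, `roc`, `n`. With single-class truth the
#'   AUC and ROC are `NA` (undefined) and reported as such.
#' @export
summary_metrics <- function(truth, scores, threshold = 0.5,
                            predicted = NULL) {
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop("`scores` and `truth` lengths differ", call. = FALSE)
  if (is.null(predicted))
    predicted <- ifelse(scores >= threshold, "fist", "rest")
  cm <- confusion_matrix(truth, predicted)
  n <- sum(cm)
  accuracy <- sum(diag(cm)) / n
  tp <- cm["fist", "fist"]; fp <- cm["rest", "fist"]; fn <- cm["fist", "rest"]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e < 1) (accuracy - p_e) / (1 - p_e) else 0
  both <- length(unique(truth)) == 2L
  structure(list(f1 = f1, kappa = kappa, accuracy = accuracy,
                 auc = if (both) auc(scores, truth) else NA_real_,
                 confusion = cm,
                 roc = if (both) roc_curve(scores, truth) else NULL,
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  accuracy %.4f | F1(fist) %.4f | kappa %.4f | AUC %s\n",
              x$accuracy, x$f1, x$kappa,
              if (is.na(x$auc)) "undefined" else sprintf("%.4f", x$auc)))
  print(x$confusion)
  invisible(x)
}

#' Average metric reports across subjects
#'
#' Arithmetic mean of each scalar metric over a list of reports, as used to
#' pool per-subject results into a single row.
#'
#' @param reports non-empty list of `metrics_report` objects.
#' @return Named numeric vector with `f1`, `kappa`, `accuracy`, `auc`.
#' @export
mean_over_subjects <- function(reports) {
  if (!length(reports)) stop("`reports` is empty", call. = FALSE)
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, TRUE, "metrics_report")))
  vapply(c("f1", "kappa", "accuracy", "auc"), function(m)
    mean(vapply(reports, function(r) r[[m]], 0)), 0)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON (scalars + confusion counts) and, optionally,
#' the confusion matrix and ROC as CSV files for plotting.
#'
#' @param report a `metrics_report`.
#' @param path JSON output path.
#' @param csv_prefix optional path prefix; writes
#'   `<prefix>_confusion.csv` and `<prefix>_roc.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, csv_prefix = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(f1 = report$f1, kappa = report$kappa,
              accuracy = report$accuracy, auc = report$auc, n = report$n,
              confusion = as.vector(report$confusion),
              confusion_order = "truth-major: rest.rest, fist.rest, rest.fist, fist.fist")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_prefix)) {
    cm <- as.data.frame(as.table(report$confusion))
    names(cm) <- c("truth", "predicted", "count")
    utils::write.csv(cm, paste0(csv_prefix, "_confusion.csv"),
                     row.names = FALSE)
    if (!is.null(report$roc))
      utils::write.csv(report$roc, paste0(csv_prefix, "_roc.csv"),
                       row.names = FALSE)
  }
  invisible(path)
}
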