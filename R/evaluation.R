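#' Binary confusion counts
#'
#' @param truth,pred Vectors of 0/1 (or logical) labels of equal length.
#' @return A named numeric vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("`truth` and `pred` lengths differ")
  truth <- as.integer(as.logical(as.integer(truth)))
  pred <- as.integer(as.logical(as.integer(pred)))
  c(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0), FN = sum(pred == 0 & truth == 1))
}

#' The four binary quality measures
#'
#' Accuracy `ACC = (TP+TN)/(TP+TN+FP+FN)`, precision `PP = TP/(TP+FP)`,
#' sensitivity `SE = TP/(TP+FN)` and specificity `SP = TN/(TN+FP)`. A
#' measure whose denominator is zero is reported as 0 by convention.
#'
#' @param cm Named vector or list with `TP`, `FP`, `TN`, `FN` counts.
#' @return A one-row tibble with columns `ACC`, `PP`, `SE`, `SP`.
#' @examples
#' binary_metrics(c(TP = 3, FP = 1, TN = 5, FN = 1))
#' @export
binary_metrics <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be >= 0")
  tot <- tp + fp + tn + fn
  if (tot == 0) abort("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    ACC = safe_div(tp + tn, tot),
    PP = safe_div(tp, tp + fp),
    SE = safe_div(tp, tp + fn),
    SP = safe_div(tn, tn + fp))
}

#' Multiclass confusion matrix with one-vs-rest reductions
#'
#' Cell `(i, j)` counts records with true class `i` predicted as class `j`.
#' Each class is then treated as positive against all others, yielding
#' per-class TP/FP/TN/FN and the four binary measures.
#'
#' @param truth,pred Equal-length label vectors.
#' @return A list with `table` (k x k count matrix, rows = truth) and
#'   `per_class` (tibble: class, TP, FP, TN, FN, ACC, PP, SE, SP).
#' @export
multiclass_confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("label vectors differ in length")
  classes <- sort(unique(c(as.character(truth), as.character(pred))))
  tf <- factor(truth, levels = classes)
  pf <- factor(pred, levels = classes)
  tab <- table(truth = tf, pred = pf)

  per_class <- purrr::map_dfr(classes, function(cl) {
    cm <- confusion_counts(tf == cl, pf == cl)
    dplyr::bind_cols(tibble::tibble(class = cl, TP = cm[["TP"]],
                                    FP = cm[["FP"]], TN = cm[["TN"]],
                                    FN = cm[["FN"]]),
                     binary_metrics(cm))
  })
  list(table = unclass(tab), per_class = per_class)
}

#' Outlier detection and over-detection accounting
#'
#' A test record is a true outlier when its label is outside the known
#' activity set A. Detection counts true outliers the model placed in its
#' outlier set; over-detection counts known-activity records wrongly flagged
#' as outliers (the negative statistic counterbalancing raw detection).
#'
#' @param result A `nestbc` object from [nest_classify()].
#' @param true_labels Optional true labels of the test records; defaults to
#'   the labels stored in the result.
#' @return A one-row tibble: `n_true_outliers`, `n_detected`,
#'   `n_overdetected`, `detection_pct` (100 * detected / true outliers, 0
#'   with `pct_undefined = TRUE` when there are no true outliers).
#' @export
outlier_report <- function(result, true_labels = NULL) {
  stopifnot(inherits(result, "nestbc"))
  truth <- if (is.null(true_labels)) result$verdicts$truth else true_labels
  if (length(truth) != nrow(result$verdicts))
    abort("`true_labels` must cover every test record")
  is_true_out <- !(truth %in% result$activities)
  is_pred_out <- result$verdicts$verdict == OUTLIER_LABEL

  n_true <- sum(is_true_out)
  n_det <- sum(is_true_out & is_pred_out)
  n_over <- sum(!is_true_out & is_pred_out)
  tibble::tibble(
    n_true_outliers = n_true,
    n_detected = n_det,
    n_overdetected = n_over,
    detection_pct = if (n_true == 0) 0 else 100 * n_det / n_true,
    pct_undefined = n_true == 0)
}

# Percentage with 2 decimals, halves rounded away from zero (table style).
format_pct <- function(x) {
  sprintf("%.2f", sign(x) * floor(abs(x) * 100 + 0.5) / 100)
}

#' Render per-level measures as a text table
#'
#' Formats the per-level ACC/PP/SE/SP of a fitted nested classifier as
#' percentages with two decimals, in the layout of the published evaluation
#' tables.
#'
#' @param result A `nestbc` object.
#' @return Character vector of table lines (also printed invisibly usable
#'   with `writeLines()`).
#' @export
render_level_table <- function(result) {
  lv <- result$levels
  header <- sprintf("%-6s %-14s %9s %10s %12s %12s",
                    "Level", "Activity", "Accuracy", "Precision",
                    "Sensitivity", "Specificity")
  rows <- sprintf("%-6s %-14s %9s %10s %12s %12s",
                  as.roman(lv$level), lv$activity,
                  format_pct(100 * lv$ACC), format_pct(100 * lv$PP),
                  format_pct(100 * lv$SE), format_pct(100 * lv$SP))
  c(header, rows)
}
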