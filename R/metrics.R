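# Confusion-matrix metrics, one-vs-rest multiclass reporting, ROC/AUC, and
# the multi-experiment report table with a Mean row.
#
# All metrics are reported as percentages:
#   accuracy    = (TP + TN) / N
#   recall      = TP / (TP + FN)
#   specificity = TN / (TN + FP)
#   precision   = TP / (TP + FP)
#   F1          = 2 * precision * recall / (precision + recall)
# A 0/0 ratio is reported as 0 and flagged degenerate rather than raising,
# so optimizers keep running on degenerate folds.

#' One-vs-rest confusion counts
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels (same length).
#' @param positive The class treated as positive; all others are negative.
#' @return A `confusion_matrix` list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) < 1) stop("empty label vectors", call. = FALSE)
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s: TP %d, TN %d, FP %d, FN %d\n",
              x$positive, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Metrics from a confusion matrix
#'
#' @param cm A [confusion_counts()] result (or a list with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return A `metrics_report` list: `accuracy`, `recall`, `specificity`,
#'   `f1_score`, `precision`, each in `[0, 100]` (percent), plus
#'   `degenerate` naming any 0/0 metrics that were reported as 0.
#' @examples
#' compute_metrics(list(tp = 50, tn = 30, fp = 10, fn = 10))
#' @export
compute_metrics <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn)
  specificity <- safe_ratio(cm$tn, cm$tn + cm$fp)
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  vals <- c(accuracy = (cm$tp + cm$tn) / n, recall = recall,
            specificity = specificity, f1_score = f1, precision = precision)
  degenerate <- names(vals)[vapply(list((cm$tp + cm$tn) / n, recall, specificity,
                                        f1, precision),
                                   function(v) isTRUE(attr(v, "degenerate")),
                                   logical(1))]
  out <- as.list(100 * as.numeric(vals))
  names(out) <- names(vals)
  out$degenerate <- degenerate
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.2f%%, recall %.2f%%, specificity %.2f%%, F1 %.2f%%, precision %.2f%%\n",
    x$accuracy, x$recall, x$specificity, x$f1_score, x$precision))
  if (length(x$degenerate)) {
    cat("  degenerate (0/0 -> 0):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-class one-vs-rest metrics table
#'
#' One row per class present in the truth (ordered by class name), each row
#' the one-vs-rest metrics with that class as positive.
#'
#' @param truth True class labels (at least 2 distinct classes).
#' @param predicted Predicted class labels.
#' @return A data frame with columns `class`, `accuracy`, `recall`,
#'   `specificity`, `f1_score`, `precision` (percent).
#' @export
per_class_report <- function(truth, predicted) {
  classes <- sort(unique(as.character(truth)))
  if (length(classes) < 2) {
    stop("per-class report needs at least 2 classes in truth", call. = FALSE)
  }
  rows <- lapply(classes, function(cl) {
    m <- compute_metrics(confusion_counts(truth, predicted, cl))
    data.frame(class = cl, accuracy = m$accuracy, recall = m$recall,
               specificity = m$specificity, f1_score = m$f1_score,
               precision = m$precision)
  })
  do.call(rbind, rows)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`) and integrates by the trapezoidal rule. The
#' resulting AUC equals the Mann-Whitney concordance statistic, ties
#' counted 1/2.
#'
#' @param scores Numeric scores for the positive class.
#' @param labels Binary truth (0/1, logical, or a 2-level factor whose
#'   second sorted level is positive).
#' @return A list with `roc` (data frame of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly 2 levels", call. = FALSE)
    labels <- as.integer(as.character(labels) == lv[2])
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Macro-average one-vs-rest AUC
#'
#' For multiclass scores, averages the one-vs-rest AUC over the classes.
#'
#' @param scores Matrix of per-class scores (columns named by class).
#' @param truth True class labels.
#' @return Numeric macro-average AUC.
#' @export
macro_auc <- function(scores, truth) {
  classes <- colnames(scores)
  aucs <- vapply(classes, function(cl) {
    roc_auc(scores[, cl], as.integer(truth == cl))$auc
  }, numeric(1))
  mean(aucs)
}

#' Multi-experiment report with a Mean row
#'
#' Assembles per-experiment metric rows (e.g. the 70-30, 80-20 and random
#' partitions) and appends a `Mean` row holding the arithmetic mean of each
#' metric column. All metric cells are rounded half-up to one decimal.
#' Column order: `Feature Selection`, `Classifier`, `Experiment`,
#' `Accuracy`, `Recall`, `Specificity`, `Precision`, `F-Score`.
#'
#' @param reports List of `metrics_report`s (or lists with the same metric
#'   fields), one per experiment.
#' @param experiments Character labels, e.g. `c("(70-30)", "(80-20)",
#'   "Random")`.
#' @param feature_selection Label for the feature-selection method
#'   (default `"None"`).
#' @param classifier Label for the classifier (default `"CNN"`).
#' @return A data frame with one row per experiment plus a `Mean` row.
#' @examples
#' r <- lapply(c(95.2, 95.8, 96.5), function(a) {
#'   list(accuracy = a, recall = a, specificity = a, f1_score = a, precision = a)
#' })
#' experiment_report(r, c("(70-30)", "(80-20)", "Random"))
#' @export
experiment_report <- function(reports, experiments,
                              feature_selection = "None", classifier = "CNN") {
  if (length(reports) < 1) stop("need at least one experiment", call. = FALSE)
  if (length(reports) != length(experiments)) {
    stop("reports and experiments must have equal length", call. = FALSE)
  }
  need <- c("accuracy", "recall", "specificity", "precision", "f1_score")
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (!all(need %in% names(r))) {
      stop("inconsistent metric columns across experiments", call. = FALSE)
    }
    data.frame(
      `Feature Selection` = feature_selection, Classifier = classifier,
      Experiment = experiments[i],
      Accuracy = round_half_up(r$accuracy), Recall = round_half_up(r$recall),
      Specificity = round_half_up(r$specificity),
      Precision = round_half_up(r$precision),
      `F-Score` = round_half_up(r$f1_score),
      check.names = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  metric_cols <- c("Accuracy", "Recall", "Specificity", "Precision", "F-Score")
  mean_row <- tab[1, ]
  mean_row$Experiment <- "Mean"
  for (cl in metric_cols) mean_row[[cl]] <- round_half_up(mean(tab[[cl]]))
  rbind(tab, mean_row)
}

#' Render a report table as aligned text
#'
#' @param report A data frame from [experiment_report()] (possibly several
#'   stacked).
#' @return A character vector of aligned lines, invisibly; also printed.
#' @export
format_report <- function(report) {
  widths <- vapply(names(report), function(nm) {
    max(nchar(nm), max(nchar(format(report[[nm]]))))
  }, numeric(1))
  fmt_row <- function(vals) {
    paste(mapply(formatC, as.character(vals), width = widths), collapse = "  ")
  }
  lines <- c(fmt_row(names(report)),
             vapply(seq_len(nrow(report)), function(i) {
               fmt_row(unlist(lapply(report[i, ], format)))
             }, character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
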