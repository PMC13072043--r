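#' Multi-class evaluation suite
#'
#' Confusion matrix (rows = actual, columns = predicted) and the standard
#' one-vs-rest metric family: per-class precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 (harmonic mean), overall accuracy (trace/total), macro
#' averages (unweighted class means) and weighted averages (true-class
#' support weights — which makes weighted recall identical to overall
#' accuracy). Zero-denominator metrics are reported as 0 and flagged.
#' Reports store full precision; rounding to 4 decimals happens only at
#' presentation.
#'
#' @name evaluation
NULL

#' Build a confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors over `class_names`.
#' @param class_names class vocabulary fixing row/column order (default:
#'   sorted union of observed labels).
#' @return a `confusion_matrix`: integer C x C matrix, rows = actual.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  class_names <- class_names %||% sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_names),
              factor(y_pred, levels = class_names))
  m <- matrix(as.integer(cm), nrow = length(class_names),
              dimnames = list(actual = class_names,
                              predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain counts matrix to a `confusion_matrix`
#' @param m square nonnegative integer matrix (rows = actual).
#' @param class_names optional class names.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m, class_names = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("confusion matrix must be square")
  if (any(m < 0) || any(m != round(m))) stopf("counts must be nonnegative integers")
  class_names <- class_names %||% rownames(m) %||%
    paste0("class", seq_len(nrow(m)))
  dimnames(m) <- list(actual = class_names, predicted = class_names)
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest metrics for a single class
#'
#' @param cm a `confusion_matrix`.
#' @param class_index 1-based class index.
#' @return list `precision`, `recall`, `f1`, `support`, `degenerate`
#'   (TRUE when any denominator was zero and the metric was defined as 0).
#' @export
class_metrics <- function(cm, class_index) {
  stopifnot(class_index >= 1, class_index <= nrow(cm))
  tp <- cm[class_index, class_index]
  fp <- sum(cm[, class_index]) - tp
  fn <- sum(cm[class_index, ]) - tp
  degenerate <- FALSE
  prec <- if (tp + fp == 0) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  rec <- if (tp + fn == 0) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  f1 <- if (prec + rec == 0) { degenerate <- TRUE; 0 } else {
    2 * prec * rec / (prec + rec)
  }
  list(precision = prec, recall = rec, f1 = f1,
       support = as.integer(sum(cm[class_index, ])), degenerate = degenerate)
}

#' Aggregate a confusion matrix into a full metrics report
#'
#' @param cm a `confusion_matrix`.
#' @return a `metrics_report`: `per_class` data.frame, `accuracy`,
#'   `macro_precision/recall/f1`, `weighted_precision/recall/f1`,
#'   `n_total`. Values are full precision; see [format()] /
#'   [metrics_to_json()] for the 4-decimal presentation.
#' @export
aggregate_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  C <- nrow(cm)
  per <- lapply(seq_len(C), function(i) class_metrics(cm, i))
  df <- data.frame(class = rownames(cm),
                   precision = vapply(per, `[[`, 0, "precision"),
                   recall = vapply(per, `[[`, 0, "recall"),
                   f1 = vapply(per, `[[`, 0, "f1"),
                   support = vapply(per, `[[`, 0L, "support"),
                   degenerate = vapply(per, `[[`, FALSE, "degenerate"),
                   row.names = NULL)
  w <- df$support / total
  structure(list(per_class = df,
                 accuracy = sum(diag(cm)) / total,
                 macro_precision = mean(df$precision),
                 macro_recall = mean(df$recall),
                 macro_f1 = mean(df$f1),
                 weighted_precision = sum(w * df$precision),
                 weighted_recall = sum(w * df$recall),
                 weighted_f1 = sum(w * df$f1),
                 n_total = as.integer(total)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df[, c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  cat(sprintf("Overall accuracy  %.*f  (n = %d)\n", digits, x$accuracy,
              x$n_total))
  cat(sprintf("Macro average     %.*f / %.*f / %.*f\n",
              digits, x$macro_precision, digits, x$macro_recall, digits,
              x$macro_f1))
  cat(sprintf("Weighted average  %.*f / %.*f / %.*f\n",
              digits, x$weighted_precision, digits, x$weighted_recall,
              digits, x$weighted_f1))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Emits both a full-precision block and a 4-decimal presentation block
#' (half-even rounding, the convention of the printed reference tables).
#'
#' @param report a `metrics_report`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return `path` or JSON string.
#' @export
metrics_to_json <- function(report, path = NULL) {
  rounded <- rapply(unclass(report),
                    function(v) if (is.double(v)) round(v, 4) else v,
                    how = "replace")
  obj <- list(full_precision = unclass(report), presentation = rounded)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a confusion matrix as CSV (class names as header row/column)
#' @param cm a `confusion_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion()]
#' @param path CSV file.
#' @return a `confusion_matrix`.
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion_matrix(as.matrix(df), class_names = rownames(df))
}

#' Per-class dataset distribution summary
#'
#' Per class: training and test counts, total, and the percentage of each
#' split (full precision; `print` shows 1 decimal, the convention of the
#' reference distribution table).
#'
#' @param labels labels for every sample.
#' @param split_assignment character/factor vector (`"train"` / `"test"`,
#'   optionally `"val"`) aligned with `labels`.
#' @return a `dataset_summary` data.frame with a `Total` row.
#' @export
dataset_summary <- function(labels, split_assignment) {
  if (length(labels) != length(split_assignment)) {
    stopf("labels and split assignment differ in length")
  }
  labels <- factor(labels)
  split <- as.character(split_assignment)
  cls <- levels(labels)
  train_n <- vapply(cls, function(c) sum(labels == c & split == "train"),
                    numeric(1))
  test_n <- vapply(cls, function(c) sum(labels == c & split == "test"),
                   numeric(1))
  df <- data.frame(class = cls, train = as.integer(train_n),
                   test = as.integer(test_n),
                   total = as.integer(train_n + test_n))
  df$train_pct <- if (sum(train_n) > 0) 100 * df$train / sum(train_n) else 0
  df$test_pct <- if (sum(test_n) > 0) 100 * df$test / sum(test_n) else 0
  total_row <- data.frame(class = "Total", train = sum(df$train),
                          test = sum(df$test), total = sum(df$total),
                          train_pct = sum(df$train_pct),
                          test_pct = sum(df$test_pct))
  structure(rbind(df, total_row), class = c("dataset_summary", "data.frame"))
}

#' @export
print.dataset_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$train_pct <- sprintf("%.1f%%", y$train_pct)
  y$test_pct <- sprintf("%.1f%%", y$test_pct)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Paired two-sided t-test on per-class metric vectors
#'
#' Classical paired t statistic `mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom. Zero variance of the differences sets the
#' `degenerate` flag (`t = 0, p = 1` when the differences are all zero).
#'
#' @param metrics_a,metrics_b equal-length paired numeric vectors (n >= 2).
#' @return list `mean_diff`, `t_statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_comparison <- function(metrics_a, metrics_b) {
  if (length(metrics_a) != length(metrics_b)) stopf("vectors must be paired")
  n <- length(metrics_a)
  if (n < 2) stopf("need at least 2 pairs")
  d <- metrics_a - metrics_b
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(mean_diff = md,
                t_statistic = if (md == 0) 0 else sign(md) * Inf,
                p_value = if (md == 0) 1 else 0,
                df = n - 1L, degenerate = TRUE))
  }
  t <- md / (s / sqrt(n))
  list(mean_diff = md, t_statistic = t,
       p_value = 2 * stats::pt(-abs(t), df = n - 1),
       df = n - 1L, degenerate = FALSE)
}
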