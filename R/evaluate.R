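#' Per-class metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. For class `c`:
#' precision is `TP_c / colsum_c`, sensitivity (recall) `TP_c / rowsum_c`
#' and F1 their harmonic mean. A zero denominator yields 0 with a
#' warning.
#'
#' @param confusion square matrix of non-negative counts.
#' @return Data frame with columns `class`, `precision`, `sensitivity`,
#'   `f1`, `support`.
#' @export
#' @examples
#' cm <- matrix(c(40, 34, 43, 1000), 2, dimnames = list(c("a","b"), c("a","b")))
#' confusion_metrics(cm)  # precision 0.54, sensitivity 0.48, F1 0.51 for "a"
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (any(confusion < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  tp <- diag(confusion)
  col_sum <- colSums(confusion)
  row_sum <- rowSums(confusion)
  if (any(col_sum == 0) || any(row_sum == 0)) {
    warning("class with zero predictions or zero support: metrics set to 0")
  }
  precision <- ifelse(col_sum == 0, 0, tp / col_sum)
  sensitivity <- ifelse(row_sum == 0, 0, tp / row_sum)
  denom <- precision + sensitivity
  f1 <- ifelse(denom == 0, 0, 2 * precision * sensitivity / denom)
  cls <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)) - 1L)
  data.frame(class = cls, precision = unname(precision),
             sensitivity = unname(sensitivity), f1 = unname(f1),
             support = unname(as.integer(row_sum)), row.names = NULL)
}

#' Evaluate a trained model on a test set
#'
#' Predictions are the argmax of the class probabilities; the report
#' holds the confusion matrix (rows true, columns predicted), overall
#' accuracy (trace over total) and per-class precision, sensitivity and
#' F1.
#'
#' @param model a `"sleep_cnn"`.
#' @param x test inputs (`"model_input"` or 3-d array).
#' @param y true labels (factor over the model's classes, or 0-based
#'   integers).
#' @return Object of class `"eval_report"`: list with `confusion`,
#'   `accuracy`, `per_class`, `n`.
#' @export
evaluate <- function(model, x, y) {
  stopifnot(inherits(model, "sleep_cnn"))
  n <- if (is.array(x)) dim(x)[1] else stop("`x` must be a 3-d array", call. = FALSE)
  if (n == 0L) stop("test set is empty", call. = FALSE)
  lab <- .encode_labels(y, model$spec$nb_class, model$classes)
  if (length(lab$y0) != n) stop("length(y) must match nrow(x)", call. = FALSE)
  pred <- predict(model, x, type = "class")
  truth <- factor(model$classes[lab$y0 + 1L], levels = model$classes)
  confusion <- table(truth, pred, dnn = c("true", "predicted"))
  confusion <- unclass(confusion)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  structure(
    list(confusion = confusion, accuracy = accuracy,
         per_class = confusion_metrics(confusion), n = n),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("<eval_report> %d test epochs, accuracy %.2f%%\n",
              x$n, 100 * x$accuracy))
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$sensitivity <- round(pc$sensitivity, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat("\nConfusion matrix (rows true, columns predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to plain-text files
#'
#' Exports the per-class metric rows and the confusion matrix as TSV.
#'
#' @param report an `"eval_report"`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_class, file.path(dir, "per_class_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- as.data.frame.matrix(report$confusion)
  cm <- cbind(true = rownames(report$confusion), cm)
  utils::write.table(cm, file.path(dir, "confusion_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("accuracy\t%.6f", report$accuracy),
             file.path(dir, "accuracy.tsv"))
  invisible(dir)
}
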