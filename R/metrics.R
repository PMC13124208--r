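#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted classes, both indexed 0-4
#' (normal, ALS, PLS, PBP, PMA) by default.
#'
#' @param true_labels integer vector of true class indices
#' @param predicted_labels integer vector of predicted class indices
#' @param n_classes number of classes (default 5)
#' @param class_names optional class names (default the MND classes)
#' @return a `confusion_matrix`: integer matrix with class-name dimnames
#' @export
confusion <- function(true_labels, predicted_labels, n_classes = 5L,
                      class_names = MND_CLASSES) {
  if (length(true_labels) != length(predicted_labels))
    stop("confusion: label vectors must have equal length")
  if (length(true_labels) &&
      (any(true_labels < 0 | true_labels >= n_classes) ||
       any(predicted_labels < 0 | predicted_labels >= n_classes)))
    stop("confusion: labels outside 0..(n_classes-1)")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = class_names[seq_len(n_classes)],
                               predicted = class_names[seq_len(n_classes)]))
  for (k in seq_along(true_labels))
    cm[true_labels[k] + 1L, predicted_labels[k] + 1L] <-
      cm[true_labels[k] + 1L, predicted_labels[k] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is `trace / total`. Per-class precision, recall and F1
#' use the one-vs-rest reduction: for class i, `TP = cm[i,i]`,
#' `FP = colsum - TP`, `FN = rowsum - TP`; precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and F1 the harmonic mean `2*Pr*Re/(Pr+Re)`. Ratios with a
#' zero denominator are reported as 0 and flagged in `undefined`. Macro
#' metrics are unweighted class means.
#'
#' @param cm a [confusion()] matrix (any square count matrix works)
#' @return a `metrics_report` list: `accuracy`, `per_class` (data frame with
#'   precision/recall/f1 and undefined flags), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `total`
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("metrics: empty confusion matrix")
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(K) - 1L),
    precision = precision, recall = recall, f1 = f1,
    precision_undefined = (tp + fp) == 0,
    recall_undefined = (tp + fn) == 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(accuracy = sum(tp) / total,
                 per_class = per_class,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f (n = %d)\n", x$accuracy, x$total))
  print(x$per_class, digits = 4)
  cat(sprintf("Macro precision %.4f | recall %.4f | F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a [metrics()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
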