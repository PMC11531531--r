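#' Confusion matrix for binary labels
#'
#' Counts true/false positives/negatives with class 1 (cancer) as the
#' positive class.
#'
#' @param truth integer vector of true labels in \{0, 1\}.
#' @param estimate integer vector of predicted labels, same length.
#' @return A `confusion_matrix`: list with counts `tp`, `tn`, `fp`, `fn`
#'   and `n`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop_input("`truth` and `estimate` must have equal length")
  }
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (!all(c(truth, estimate) %in% c(0L, 1L))) {
    stop_input("labels must be 0 or 1")
  }
  structure(
    list(
      tp = sum(truth == 1L & estimate == 1L),
      tn = sum(truth == 0L & estimate == 0L),
      fp = sum(truth == 0L & estimate == 1L),
      fn = sum(truth == 1L & estimate == 0L),
      n = length(truth)
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  print(m)
  invisible(x)
}

# Metrics of one 2x2 table with the given positive orientation.
binary_metrics <- function(tp, tn, fp, fn) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  tibble(
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    precision = precision,
    recall = recall,
    specificity = safe(tn, tn + fp),
    f1 = safe(2 * tp, 2 * tp + fp + fn)
  )
}

#' Classification metric suite
#'
#' Computes accuracy, precision, recall (sensitivity/TPR), specificity
#' (TNR) and F1 (`2TP / (2TP + FP + FN)`) from a confusion matrix — once
#' per class (each class treated as positive in turn) and as the
#' unweighted macro average of the two class rows. A ratio with a zero
#' denominator is reported as `NA` (undefined), never silently as 0.
#'
#' @param cm a [confusion()] matrix, or a vector of true labels (then
#'   `estimate` must be given and the matrix is built first).
#' @param estimate optional predicted labels when `cm` is a label vector.
#' @return A `metric_report` tibble with rows `class_1`, `class_0`,
#'   `macro_average` and the five metric columns.
#' @export
#' @examples
#' classification_metrics(confusion(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 1)))
classification_metrics <- function(cm, estimate = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- confusion(cm, estimate)
  }
  pos1 <- binary_metrics(cm$tp, cm$tn, cm$fp, cm$fn)
  pos0 <- binary_metrics(cm$tn, cm$tp, cm$fn, cm$fp)  # class 0 as positive
  avg <- as_tibble(as.list(colMeans(rbind(pos1, pos0))))
  out <- bind_rows(pos1, pos0, avg)
  out <- mutate(out, class = c("class_1", "class_0", "macro_average"),
                .before = 1L)
  class(out) <- c("metric_report", class(out))
  out
}

#' Tidy a metric report into long form
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return A long tibble with columns `class`, `metric`, `value`.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"class",
                      names_to = "metric", values_to = "value")
}

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object a `confusion_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble(
    truth = factor(c(0, 0, 1, 1)),
    predicted = factor(c(0, 1, 0, 1)),
    count = c(object$tn, object$fp, object$fn, object$tp)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
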