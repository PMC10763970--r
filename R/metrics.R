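#' Multi-class confusion matrix
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`.
#'
#' @param y_true integer label vector.
#' @param y_pred integer label vector of the same length.
#' @param class_map ordered character vector of class codes; labels index
#'   into it.
#' @return An object of class `confusion` with elements `counts` (C x C
#'   integer matrix with class codes as dimnames) and `class_map`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_map) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  C <- length(class_map)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true >= 1 & y_true <= C), all(y_pred >= 1 & y_pred <= C))
  counts <- matrix(0L, C, C, dimnames = list(true = class_map,
                                             predicted = class_map))
  for (i in seq_along(y_true))
    counts[y_true[i], y_pred[i]] <- counts[y_true[i], y_pred[i]] + 1L
  structure(list(counts = counts, class_map = as.character(class_map)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion>", sum(x$counts), "samples\n")
  print(x$counts)
  invisible(x)
}

#' Per-class one-vs-rest precision, recall and F1
#'
#' Each class in turn is treated as positive and all others as negative:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2*precision*recall/(precision+recall). Any zero denominator yields 0
#' (the documented convention for classes never predicted or never present).
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  m <- cm$counts
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(class = cm$class_map, precision = unname(prec),
             recall = unname(rec), f1 = unname(f1),
             support = unname(rowSums(m)), stringsAsFactors = FALSE)
}

#' Macro-average per-class metrics
#'
#' Unweighted arithmetic mean of the per-class scores: every class counts
#' equally regardless of support, so minority-class failures are not masked
#' by a large majority class.
#'
#' @param per_class data.frame from [per_class_metrics()].
#' @return Named numeric vector `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
macro_average <- function(per_class) {
  if (!nrow(per_class)) stop("no classes to average", call. = FALSE)
  c(macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1))
}

#' Overall accuracy from a confusion matrix
#'
#' trace/total: the fraction of correctly predicted samples (equal to the
#' micro-averaged accuracy).
#'
#' @param cm a [confusion_matrix()].
#' @return Fraction in \eqn{[0, 1]}.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm$counts)) / total
}

#' Full metric report for a prediction vector
#'
#' @param y_true,y_pred integer label vectors.
#' @param class_map ordered character vector of class codes.
#' @return An object of class `metric_report`: `accuracy`, `per_class`,
#'   `macro_precision`, `macro_recall`, `macro_f1` and the underlying
#'   `confusion`.
#' @export
metric_report <- function(y_true, y_pred, class_map) {
  cm <- confusion_matrix(y_true, y_pred, class_map)
  pc <- per_class_metrics(cm)
  mac <- macro_average(pc)
  structure(list(accuracy = accuracy(cm), per_class = pc,
                 macro_precision = unname(mac["macro_precision"]),
                 macro_recall = unname(mac["macro_recall"]),
                 macro_f1 = unname(mac["macro_f1"]),
                 confusion = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cat(sprintf("<metric_report> accuracy %.3f\n", x$accuracy))
  pc <- x$per_class
  pc$precision <- round_half_up(pc$precision, digits)
  pc$recall <- round_half_up(pc$recall, digits)
  pc$f1 <- round_half_up(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("macro: precision %.2f  recall %.2f  F1 %.2f\n",
              round_half_up(x$macro_precision, digits),
              round_half_up(x$macro_recall, digits),
              round_half_up(x$macro_f1, digits)))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean, with the zero-denominator convention F1 = 0 when
#' precision = recall = 0.
#'
#' @param precision,recall fractions in \eqn{[0, 1]}.
#' @return F1 fraction.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Round half away from zero
#'
#' Report tables round half-up (0.995 -> 1.00 at two decimals), unlike base
#' [round()]'s round-half-even, so printed-table comparisons are
#' well-defined.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 nudge keeps exact halves that lose a ulp in binary (e.g. 0.865)
  # on the half-up side; metric values are O(1) so it changes nothing else
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
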