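#' Per-class confusion tally
#'
#' One-vs-rest true-positive / false-positive / false-negative counts per
#' class. The class set is the union of observed and predicted labels,
#' ordered lexicographically, so a model that predicts a label absent from
#' the truth is still penalised.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels, same length.
#' @return A `kb_tally`: tibble with columns `class`, `tp`, `fp`, `fn`,
#'   `support`.
#' @examples
#' confusion_tally(c("A", "A", "B"), c("A", "B", "B"))
#' @export
confusion_tally <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    kb_stop(paste0("length mismatch: ", length(truth), " true vs ",
                   length(predicted), " predicted labels"),
            "kbalance_type_error")
  }
  if (length(truth) < 1) kb_stop("empty label vectors", "kbalance_empty_input")
  classes <- sort(unique(c(truth, predicted)))
  t_f <- factor(truth, levels = classes)
  p_f <- factor(predicted, levels = classes)
  tp <- vapply(classes, function(cl) sum(truth == cl & predicted == cl), 0L)
  support <- as.integer(table(t_f))
  pred_n <- as.integer(table(p_f))
  out <- tibble(
    class = classes,
    tp = as.integer(tp),
    fp = pred_n - as.integer(tp),
    fn = support - as.integer(tp),
    support = support
  )
  class(out) <- c("kb_tally", class(out))
  out
}

#' Macro-average precision (MAP)
#'
#' The mean over all classes of per-class precision
#' \eqn{TP_i / (TP_i + FP_i)}. A class that is never predicted
#' (\eqn{TP_i + FP_i = 0}) contributes precision 0 and is counted in
#' `n_undefined`, so never predicting a class is penalised rather than
#' ignored; `n_undefined` lets users recompute the drop-from-mean variant.
#'
#' @param x A `kb_tally` from [confusion_tally()], or a vector of true
#'   labels (then `predicted` must be given).
#' @param predicted Predicted labels, when `x` is a vector of true labels.
#' @return A `kb_map_report`: list with `map` (in `[0,1]`), `per_class`
#'   (tibble: class, precision, tp, fp, support) and `n_undefined`.
#'   `glance()` gives a one-row summary, `tidy()` the per-class table.
#' @examples
#' macro_average_precision(c("A", "A", "B"), c("A", "B", "B"))
#' @export
macro_average_precision <- function(x, predicted = NULL) {
  tally <- if (inherits(x, "kb_tally")) x else confusion_tally(x, predicted)
  denom <- tally$tp + tally$fp
  undefined <- denom == 0
  precision <- ifelse(undefined, 0, tally$tp / pmax(denom, 1L))
  per_class <- tibble(
    class = tally$class,
    precision = precision,
    tp = tally$tp,
    fp = tally$fp,
    support = tally$support
  )
  structure(
    list(
      map = mean(precision),
      per_class = per_class,
      n_undefined = sum(undefined)
    ),
    class = "kb_map_report"
  )
}

#' @export
print.kb_map_report <- function(x, ...) {
  cat("<kb_map_report> macro-average precision = ",
      format(x$map, digits = 4), " over ", nrow(x$per_class),
      " classes (", x$n_undefined, " never predicted)\n", sep = "")
  invisible(x)
}

#' @method tidy kb_map_report
#' @export
tidy.kb_map_report <- function(x, ...) x$per_class

#' @method glance kb_map_report
#' @export
glance.kb_map_report <- function(x, ...) {
  tibble(map = x$map, n_classes = nrow(x$per_class),
         n_undefined = x$n_undefined)
}

#' @method autoplot kb_map_report
#' @export
autoplot.kb_map_report <- function(object, ...) {
  d <- object$per_class
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$precision)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$map, linetype = 2) +
    ggplot2::labs(x = NULL, y = "precision",
                  title = paste0("Per-class precision (MAP = ",
                                 format(object$map, digits = 3), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
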