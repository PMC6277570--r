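#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_vline labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a weight scan: SE, SP and ACC against the positive-loss weight
#'
#' The vertical line marks the selected weight — the interpolated
#' crossing of the sensitivity and specificity curves (or the
#' smallest-gap grid point when they never cross).
#'
#' @param object A `weight_scan` from [scan_weights()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.weight_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("w", "acc", "se", "sp")],
                              -"w", names_to = "index",
                              values_to = "value")
  long$index <- toupper(long$index)
  ggplot(long, aes(x = .data$w, y = .data$value,
                   colour = .data$index)) +
    geom_line() +
    geom_point(size = 1) +
    geom_vline(xintercept = attr(object, "selected_w"),
               linetype = "dashed") +
    labs(x = "positive-sample loss weight w", y = "validation index",
         colour = NULL,
         title = "Sensitivity/specificity trade-off across loss weights") +
    theme_minimal()
}

#' Plot a training trace
#'
#' @param object A trained `dl_classifier` (or any object with a
#'   `trace` tibble holding `epoch`, `loss`, `monitored`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dl_classifier <- function(object, ...) {
  if (is.null(object$trace)) abort("no training trace available")
  long <- tidyr::pivot_longer(object$trace, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Classifier training trace") +
    theme_minimal()
}

#' ROC curve for a labeled prediction set
#'
#' @param labels Binary 0/1 truth vector.
#' @param probabilities Predicted probabilities.
#' @return A ggplot object with the empirical ROC curve and its AUC in
#'   the title.
#' @export
plot_roc <- function(labels, probabilities) {
  labels <- .check_labels(labels, "labels")
  ord <- order(probabilities, decreasing = TRUE)
  y <- labels[ord]
  tpr <- c(0, cumsum(y == 1L) / sum(y == 1L))
  fpr <- c(0, cumsum(y == 0L) / sum(y == 0L))
  ggplot(tibble(fpr = fpr, tpr = tpr), aes(.data$fpr, .data$tpr)) +
    geom_line() +
    ggplot2::geom_abline(linetype = "dotted") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUC = %.3f)",
                         auc_mw(labels, probabilities))) +
    theme_minimal()
}
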