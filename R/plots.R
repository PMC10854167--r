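# ggplot2 views of the main result types. Kept deliberately plain: tiles
# for confusion matrices, bars/points elsewhere, no theme opinions.

#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy(object)
  d$true <- factor(d$true, levels = rev(object$classes))
  d$predicted <- factor(d$predicted, levels = object$classes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$row_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0,
                                                   sprintf("%.0f", .data$row_pct),
                                                   "")), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 name = "row %") +
    ggplot2::labs(x = "predicted class", y = "true class")
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$metrics, -"class", names_to = "metric",
                           values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot diff_meth
#' @export
autoplot.diff_meth <- function(object, ...) {
  d <- dplyr::filter(object, .data$evaluable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$max_abs_delta,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = expression(max ~ "|" * Delta * beta * "|"),
                  y = expression(-log[10] ~ p), colour = "candidate")
}

#' @method autoplot panel_selection
#' @export
autoplot.panel_selection <- function(object, top = 30, ...) {
  d <- head(object$final_importance, top)
  d$probe_id <- factor(d$probe_id, levels = rev(d$probe_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$probe_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL)
}

#' @method autoplot panel_sweep
#' @export
autoplot.panel_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "panel size (top-k probes)", y = "validation accuracy")
}

#' @method autoplot panel_annotation
#' @export
autoplot.panel_annotation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~categorization, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = NULL, y = "fraction of panel") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
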