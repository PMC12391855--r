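# Dot-and-interval displays of the inequality report.

#' Plot inequalities with and without the hypothetical intervention
#'
#' Dot-and-interval panel in the style of the study's summary figure: per
#' predictor level, the point estimate of the inequality in weeks before
#' (dark) and after (light) the intervention, with its bootstrap interval;
#' reference levels sit at zero without intervals.
#'
#' @param table2 The report tibble from [run_full_analysis()] (or
#'   [tidy()] of an `ineq_analysis`).
#' @return A ggplot object.
#' @export
plot_inequalities <- function(table2) {
  long <- dplyr::bind_rows(
    dplyr::transmute(table2, predictor = .data$predictor, level = .data$level,
                     is_reference = .data$is_reference,
                     scenario = "without intervention",
                     estimate = .data$beta_without,
                     lo = .data$ci_without_low, hi = .data$ci_without_high),
    dplyr::transmute(table2, predictor = .data$predictor, level = .data$level,
                     is_reference = .data$is_reference,
                     scenario = "with intervention",
                     estimate = .data$beta_with,
                     lo = .data$ci_with_low, hi = .data$ci_with_high))
  long <- dplyr::filter(long, !is.na(.data$estimate))
  long$scenario <- factor(long$scenario,
                          levels = c("without intervention", "with intervention"))
  long$label <- paste(long$predictor, long$level, sep = ": ")
  long$label <- factor(long$label, levels = rev(unique(long$label)))

  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$label,
                                     colour = .data$scenario)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      data = dplyr::filter(long, !.data$is_reference),
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        size = 1.6) +
    ggplot2::scale_colour_manual(values = c("without intervention" = "#08306b",
                                            "with intervention" = "#6baed6")) +
    ggplot2::labs(x = "difference in initiation timing (weeks vs reference)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname plot_inequalities
#' @param object An `ineq_analysis`.
#' @param ... Unused.
#' @export
autoplot.ineq_analysis <- function(object, ...) {
  plot_inequalities(object$table2)
}

#' Trace plot of imputed-variable means across chained iterations
#'
#' One line per imputation chain per variable: the mean of the imputed cells
#' after each sweep. Flat, well-mixed traces indicate the chains have
#' settled.
#'
#' @param imputed An `imputed_sets` object.
#' @return A ggplot object.
#' @export
plot_imputation_trace <- function(imputed) {
  stopifnot(inherits(imputed, "imputed_sets"))
  ggplot2::ggplot(imputed$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$mean,
                               group = .data$imputation)) +
    ggplot2::geom_line(alpha = 0.5, colour = "#08306b") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "chained-equation iteration",
                  y = "mean of imputed cells") +
    ggplot2::theme_minimal(base_size = 9)
}
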