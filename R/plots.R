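# ggplot2 views of the diagnostic tables. Each function draws from the
# tables produced by mr_plot_tables() / mr_leave_one_out() so the plotted
# numbers and the exported TSVs are the same.

#' Scatter plot of instrument effects with fitted causal lines
#'
#' @param data Harmonized instrument table.
#' @param estimates A list of `mr_estimate` objects whose fitted lines are
#'   overlaid (IVW lines pass through the origin; MR-Egger keeps its
#'   intercept).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(data, estimates) {
  tabs <- mr_plot_tables(data, estimates)
  ggplot2::ggplot(tabs$scatter, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(data = tabs$lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-SNP Wald ratios and pooled estimates
#'
#' @inheritParams plot_mr_scatter
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(data, estimates) {
  forest <- mr_plot_tables(data, estimates)$forest
  forest$label <- factor(forest$label, levels = rev(forest$label))
  ggplot2::ggplot(forest, ggplot2::aes(x = .data$beta, y = .data$label,
                                       colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate (log OR per exposure unit)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot of per-SNP ratios against precision
#'
#' @inheritParams plot_mr_scatter
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(data, estimates) {
  tabs <- mr_plot_tables(data, estimates)
  ggplot2::ggplot(tabs$funnel, ggplot2::aes(x = .data$beta_ratio,
                                            y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = tabs$lines,
                        ggplot2::aes(xintercept = .data$slope,
                                     colour = .data$method)) +
    ggplot2::labs(x = "Per-SNP causal estimate", y = "Precision (1/SE)",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Leave-one-out influence plot
#'
#' @param loo A leave-one-out table from [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_mr_loo <- function(loo) {
  assert_columns(loo, c("snp_excluded", "beta", "ci_low", "ci_high"),
                 what = "leave-one-out table")
  loo$snp_excluded <- factor(loo$snp_excluded, levels = rev(loo$snp_excluded))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$snp_excluded)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate omitting the SNP", y = "SNP omitted") +
    ggplot2::theme_minimal()
}

#' Autoplot method for harmonized MR datasets
#'
#' Draws the scatter plot with IVW and (when J >= 3) MR-Egger lines.
#'
#' @param object An `mr_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_dataset <- function(object, ...) {
  ests <- list(mr_ivw(object))
  if (nrow(object) >= 3) ests <- c(ests, list(mr_egger(object)))
  plot_mr_scatter(object, ests)
}
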