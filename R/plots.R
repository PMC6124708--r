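#' Plot an ROC curve
#'
#' @param object An `osa_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: the empirical ROC curve with the chance diagonal and
#'   the AUC in the subtitle.
#' @method autoplot osa_roc
#' @export
autoplot.osa_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.3f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity-specificity cut-off sweep
#'
#' @param object An `osa_sweep` from [cutoff_sweep()].
#' @param ... Unused.
#' @return A ggplot of both metrics against the score cut-off, with the
#'   crossover cut-off marked.
#' @method autoplot osa_sweep
#' @export
autoplot.osa_sweep <- function(object, ...) {
  cross <- attr(object, "crossover")
  ggplot2::ggplot(tidy.osa_sweep(object),
                  ggplot2::aes(x = .data$cutoff, y = .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = cross, linetype = "dotted") +
    ggplot2::annotate("text", x = cross, y = 0.02, hjust = -0.1,
                      label = sprintf("crossover %.2f", cross), size = 3) +
    ggplot2::labs(x = "Score cut-off", y = "Proportion", colour = NULL,
                  title = "Sensitivity-specificity interplay over score cut-offs") +
    ggplot2::theme_minimal()
}

#' Plot a sub-score lookup chart
#'
#' @param object A `sas_subscore_table` from [subscore_table()].
#' @param ... Unused.
#' @return A ggplot of the linear sub-score chart with the reference value
#'   (sub-score 1) highlighted.
#' @method autoplot sas_subscore_table
#' @export
autoplot.sas_subscore_table <- function(object, ...) {
  ref <- attr(object, "reference")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$input, y = .data$subscore)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = ref, colour = "black", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, colour = "black", linetype = "dashed") +
    ggplot2::labs(x = attr(object, "component"), y = "sub-score",
                  title = sprintf("Sub-score chart (%s; reference = %g)",
                                  attr(object, "component"), ref)) +
    ggplot2::theme_minimal()
}

#' Plot a severity scorecard
#'
#' @param object A `sas_scorecard` from [scorecard_grid()].
#' @param ... Unused.
#' @return A ggplot tile grid: BMI by neck-circumference bins, faceted by
#'   blood-pressure and Epworth bins, filled by risk band and labelled
#'   with the cell score.
#' @method autoplot sas_scorecard
#' @export
autoplot.sas_scorecard <- function(object, ...) {
  band_fill <- c(Low = "#4daf4a", Mild = "#a6d854", Moderate = "#ffd92f",
                 High = "#fc8d62", "Very high" = "#e41a1c")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$nc_bin, y = .data$bmi_bin,
                               fill = .data$sas_band)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$sas_score)),
                       size = 2.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$bp_bin),
                        cols = ggplot2::vars(.data$ess_bin)) +
    ggplot2::scale_fill_manual(values = band_fill, drop = FALSE) +
    ggplot2::labs(x = "Neck circumference bin (cm)", y = "BMI bin (kg/m2)",
                  fill = "Risk band",
                  title = sprintf("Severity scorecard (%s)", attr(object, "sex"))) +
    ggplot2::theme_minimal()
}
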