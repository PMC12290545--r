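#' Plot chance-level curves
#'
#' Shows the per-position chance-level absolute error (U-shaped) and signed
#' error (linear, slope -1) side by side.
#'
#' @param object A `chance_curves` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chance_curves
#' @export
autoplot.chance_curves <- function(object, ...) {
  long <- as_tibble(object) |>
    select("position", "abs_error", "signed_error") |>
    tidyr::pivot_longer(-"position", names_to = "metric", values_to = "error") |>
    mutate(metric = dplyr::recode(.data$metric,
                                  abs_error = "absolute error",
                                  signed_error = "signed error"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      x = "serial position",
      y = "chance-level error (positions)",
      title = sprintf("Chance-level timeline error (%s)", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot ANOVA effect sizes
#'
#' @param object A `tl_anova` object.
#' @param ... Unused.
#' @return A ggplot of partial eta squared per effect.
#' @method autoplot tl_anova
#' @export
autoplot.tl_anova <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$term, .data$partial_eta_sq),
                                    y = .data$partial_eta_sq)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(partial ~ eta^2),
                  title = sprintf("Repeated-measures ANOVA: %s", object$dv)) +
    ggplot2::theme_minimal()
}

#' Plot subject-cell performance by condition and position class
#'
#' Mean and standard error of a cell metric across subjects, split by
#' condition and position class.
#'
#' @param cells Subject-cell table from [aggregate_cells()].
#' @param dv Which cell column to plot (default `"mean_accuracy"`).
#' @return A ggplot.
#' @export
plot_performance <- function(cells, dv = "mean_accuracy") {
  assert_columns(cells, c("condition", "position_class", dv), "`cells`")
  summ <- cells |>
    filter(!is.na(.data[[dv]])) |>
    group_by(.data$condition, .data$position_class) |>
    summarise(mean = mean(.data[[dv]]),
              se = sd(.data[[dv]]) / sqrt(n()),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$position_class, y = .data$mean,
                                     color = .data$condition,
                                     group = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "position class", y = dv) +
    ggplot2::theme_minimal()
}
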