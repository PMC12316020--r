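#' Coefficient plot for a family-clustered model fit
#'
#' Forest-style plot of fixed-effect estimates with 95% Wald intervals.
#'
#' @param object A `twinclock_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twinclock_fit
#' @export
autoplot.twinclock_fit <- function(object, ...) {
  d <- object$terms
  d <- d[d$term != "(Intercept)", , drop = FALSE]
  d$lo <- d$estimate - 1.96 * d$std_error
  d$hi <- d$estimate + 1.96 * d$std_error
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term,
                                                     .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(
      x = "Standardized coefficient (95% CI)", y = NULL,
      title = sprintf("%s ~ %s (%s model, n = %d)",
                      object$response, object$exposure, object$model,
                      object$n)) +
    ggplot2::theme_minimal()
}

#' Brain-age gap before and after age-bias correction
#'
#' Scatter of the raw and corrected gap against chronological age with OLS
#' trend lines; after correction the trend is flat by construction.
#'
#' @param records Output of [beheshti_correct()].
#' @return A ggplot object.
#' @export
plot_bag_correction <- function(records) {
  stopifnot_columns(records, c("chron_age", "bag_raw", "bag_corrected"),
                    "records")
  long <- tidyr::pivot_longer(
    records[, c("chron_age", "bag_raw", "bag_corrected")],
    cols = c("bag_raw", "bag_corrected"),
    names_to = "stage", values_to = "bag")
  long$stage <- factor(long$stage, levels = c("bag_raw", "bag_corrected"),
                       labels = c("raw", "age-bias corrected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chron_age, y = .data$bag)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "blue") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Brain-age gap (years)") +
    ggplot2::theme_minimal()
}

#' Within-MZ-pair difference scatter
#'
#' Plots within-pair differences in brain-age acceleration against
#' within-pair differences in a clock's acceleration, with the no-intercept
#' regression fit whose slope estimates the unique-environment cross-trait
#' correlation.
#'
#' @param pairs An MZ pair table from [make_pairs()].
#' @param trait_x_label,trait_y_label Axis labels.
#' @return A ggplot object.
#' @export
plot_mz_differences <- function(pairs,
                                trait_x_label = "Δ DNAm age acceleration",
                                trait_y_label = "Δ brain age acceleration") {
  d <- tibble(dx = pairs$x1 - pairs$x2, dy = pairs$y1 - pairs$y2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x - 1,
                         colour = "blue") +
    ggplot2::labs(x = trait_x_label, y = trait_y_label) +
    ggplot2::theme_minimal()
}
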