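#' Forest-style plot of a synergy report
#'
#' DL estimates with 95% t confidence intervals per combination, colored
#' by the synergy call; the dashed line marks the additive null (DL = 0).
#'
#' @param object A `synergy_tbl` from [synergy_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synergy_tbl
#' @export
autoplot.synergy_tbl <- function(object, ...) {
  d <- dplyr::mutate(object,
                     lo = .data$dl - qt(0.975, .data$df) * .data$se,
                     hi = .data$dl + qt(0.975, .data$df) * .data$se)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dl, y = .data$treatment,
                                  color = .data$call)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "DL (log10 units)", y = NULL, color = "Call") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier survival curves
#'
#' Step curves per treatment group with censoring marks.
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  curve <- tidy(object)
  # prepend S(0) = 1 for each group so steps start at full survival
  start <- dplyr::distinct(curve, .data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  steps <- dplyr::bind_rows(start,
                            dplyr::select(curve, "group", "time",
                                          "estimate")) |>
    dplyr::arrange(.data$group, .data$time)
  cens <- dplyr::filter(curve, .data$n_censor > 0)
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$estimate,
                                      color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days post-treatment", y = "Survival probability",
                  color = "Group") +
    ggplot2::theme_minimal()
}

#' Tumor growth curves per group
#'
#' Group mean volume with standard-error ribbons against day.
#'
#' @param summary_tbl Output of [growth_summary()].
#' @return A ggplot object.
#' @export
plot_growth_summary <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(.data$day, .data$mean_volume,
                               color = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_volume - .data$se_volume,
                   ymax = .data$mean_volume + .data$se_volume),
      alpha = 0.2, color = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Days post-treatment", y = "Tumor volume (mm^3)",
                  color = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Standard-curve diagnostic plot
#'
#' Calibration points with the fitted least-squares line.
#'
#' @param object A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$quantity, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, color = "steelblue") +
    ggplot2::labs(x = "Known quantity", y = "Measured signal") +
    ggplot2::theme_minimal()
}
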