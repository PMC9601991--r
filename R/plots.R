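#' @export
autoplot.exvivo_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$true_volume_cm3,
                               y = .data$measured_volume_cm3)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Reference volume (cm³)",
      y = "Slice-stack volumetry (cm³)",
      title = "Phantom volumetry validation",
      subtitle = sprintf("Pearson r = %.3f", object$r)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_result <- function(object, ...) {
  labs <- object$correlations |>
    dplyr::mutate(label = sprintf("%s (r = %.2f)", .data$group, .data$r))
  d <- dplyr::left_join(object$cohort, labs, by = "group")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured_volume_cm3,
                                  y = .data$or_value,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "3D muscle volume (cm³)",
                  y = "Y-view occupation ratio",
                  colour = NULL,
                  title = "Occupation ratio vs muscle volume by group") +
    ggplot2::theme_minimal()
}

#' Plot an occupation-ratio retraction sweep
#'
#' Visualises the medialization mechanism from a [retraction_sweep()]
#' table: the occupation ratio falls with belly retraction while the 3D
#' volume stays flat.
#'
#' @param sweep tibble from [retraction_sweep()].
#' @return a ggplot object.
#' @export
plot_retraction_sweep <- function(sweep) {
  d <- sweep |>
    dplyr::mutate(volume_rel = .data$volume_cm3 /
                    .data$volume_cm3[1],
                  or_rel = .data$or_value / .data$or_value[1]) |>
    tidyr::pivot_longer(c("volume_rel", "or_rel"),
                        names_to = "metric", values_to = "relative")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$retraction_mm,
                                  y = .data$relative,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(
      labels = c(or_rel = "Y-view occupation ratio",
                 volume_rel = "3D muscle volume")) +
    ggplot2::labs(x = "Medial belly retraction (mm)",
                  y = "Relative to no retraction", colour = NULL,
                  title = "Retraction suppresses the occupation ratio, not the volume") +
    ggplot2::theme_minimal()
}
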