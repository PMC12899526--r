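#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weight trajectory
#'
#' @param object A `ssbtax_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ssbtax_trajectory
#' @export
autoplot.ssbtax_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$delta_weight)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years since intervention", y = "Weight change (kg)",
                  title = sprintf("Sustained intake change of %.0f kJ/day",
                                  attr(object, "delta_EI"))) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo uncertainty intervals
#'
#' @param object A `ssbtax_mc`.
#' @param measures Optional subset of measures to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ssbtax_mc
#' @export
autoplot.ssbtax_mc <- function(object, measures = NULL, ...) {
  df <- tidy(object)
  if (!is.null(measures)) df <- df[df$measure %in% measures, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$measure,
                                   xmin = .data$lo95, xmax = .data$hi95,
                                   colour = .data$sex)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Mean (95% uncertainty interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cases averted per 100,000 by disease
#'
#' @param delta A `ssbtax_delta`.
#' @return A ggplot.
#' @export
plot_cases_averted <- function(delta) {
  df <- tidy(delta)
  df <- df[grepl("^cases_averted_per_100k_", df$measure), ]
  df$disease <- sub("^cases_averted_per_100k_", "", df$measure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$disease,
                                   fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Cases averted per 100,000 adults", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot baseline vs post-tax overweight/obesity prevalence
#'
#' @param prev Output of [prevalence_table()].
#' @return A ggplot.
#' @export
plot_prevalence <- function(prev) {
  df <- tidyr::pivot_longer(prev, c("overweight", "obesity"),
                            names_to = "class", values_to = "prevalence")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group, y = .data$prevalence,
                                   colour = .data$scenario, group = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(.data$class ~ .data$sex) +
    ggplot2::labs(x = "Age group", y = "Prevalence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
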