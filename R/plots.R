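#' Plot a log-linear growth fit
#'
#' Yearly counts on a log scale with the fitted exponential trend line.
#'
#' @param object A `growth_fit` from [fit_loglinear()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  if (is.null(object$series)) {
    abort("cannot plot a coefficient-only growth fit (no series)")
  }
  df <- object$series
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_function(
      fun = function(x) exp(object$a + object$b * x),
      colour = "#2166ac"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Year", y = "Research articles (log scale)",
      title = sprintf("ln(y) = %.3f + %.3f x", object$a, object$b)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a trend matrix
#'
#' The correlation-matrix view: tumor groups on the x axis, topics on the y
#' axis, point size by article count, colour by trend category.
#'
#' @param object A `trend_matrix` from [trend_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trend_matrix <- function(object, ...) {
  df <- object %>%
    mutate(topic = tidyr::replace_na(.data$topic, "(trend)")) %>%
    filter(.data$n_total > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$topic,
    size = .data$n_total, colour = .data$category
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      high = "#e08214", moderate = "#999999", low = "#2166ac",
      new = "#b2182b", empty = "#eeeeee"
    )) +
    ggplot2::labs(x = "Tumor group", y = "Research topic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-country research activity
#'
#' Fractional publication counts by country, optionally population-adjusted.
#'
#' @param geography Tibble from [aggregate_geography()].
#' @param per_capita Plot fractional counts per million inhabitants instead
#'   of raw fractional sums.
#' @param top_n Keep the `top_n` most active countries.
#' @return A ggplot object.
#' @export
plot_country_activity <- function(geography, per_capita = FALSE, top_n = 15) {
  metric <- if (per_capita) "frac_per_million" else "frac_sum"
  df <- geography %>%
    filter(.data$country != "ERA") %>%
    arrange(dplyr::desc(.data[[metric]])) %>%
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$country, .data[[metric]]),
    y = .data[[metric]], fill = .data$era_member
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = if (per_capita) "Fractional count per million inhabitants" else "Fractional count",
      fill = "ERA"
    ) +
    ggplot2::theme_minimal()
}
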