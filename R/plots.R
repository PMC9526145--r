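#' Plot attributable burden rates by region and approach
#'
#' Bar chart of attributable burden per 100,000 population, faceted by
#' measure, with one bar per estimation approach within each region —
#' the standard regional comparison view for this kind of analysis.
#'
#' @param aggregated output of [aggregate_attribution()] with a
#'   `rate_per_100k` column (i.e. called with `population`).
#' @return a ggplot object.
#' @export
plot_attribution <- function(aggregated) {
  if (!"rate_per_100k" %in% names(aggregated)) {
    abort("`aggregated` needs a `rate_per_100k` column; pass `population` to aggregate_attribution().")
  }
  ggplot2::ggplot(
    aggregated,
    ggplot2::aes(x = .data$group, y = .data$rate_per_100k,
                 fill = .data$approach)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Attributable burden per 100,000 population",
      fill = "Approach",
      title = "Burden attributable to mental disorders, by region and approach"
    ) +
    ggplot2::theme_minimal()
}

#' Plot economic value as a percent of GDP by region
#'
#' @param pct output of [percent_of_gdp()] with a regional grouping.
#' @return a ggplot object.
#' @export
plot_pct_gdp <- function(pct) {
  ggplot2::ggplot(
    pct,
    ggplot2::aes(x = .data$group, y = .data$pct_gdp, fill = .data$approach)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Economic value (% of GDP)", fill = "Approach",
      title = "Economic value associated with mental disorders, % of GDP"
    ) +
    ggplot2::theme_minimal()
}

#' Plot method for valuation results
#' @param object an `mh_valuation` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mh_valuation
#' @export
autoplot.mh_valuation <- function(object, ...) {
  d <- object %>%
    group_by(.data$approach, .data$scheme) %>%
    summarise(value_usd = sum(.data$value_usd), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$approach, y = .data$value_usd / 1e12,
                                  fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Approach", y = "Value (trillions)", fill = "Scheme") +
    ggplot2::theme_minimal()
}
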