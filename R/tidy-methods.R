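#' @importFrom ggplot2 autoplot
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a synthetic world into its burden table
#'
#' @param x an `mh_world` object.
#' @param ... unused.
#' @return the canonical burden tibble.
#' @method tidy mh_world
#' @export
tidy.mh_world <- function(x, ...) x$burden

#' One-row summary of a synthetic world
#'
#' @param x an `mh_world` object.
#' @param ... unused.
#' @return a one-row tibble: country/region counts, total DALYs, mean
#'   prevalence, and the planted gradient and relative risks.
#' @method glance mh_world
#' @export
glance.mh_world <- function(x, ...) {
  tibble(
    n_countries = x$config$n_countries,
    n_regions = x$config$n_regions,
    n_causes = dplyr::n_distinct(x$burden$cause),
    total_dalys = sum(x$burden$val[x$burden$measure == "DALYs" &
                                     x$burden$cause == "All causes"]),
    mean_prevalence = mean(x$ground_truth$prevalence),
    income_gradient = x$config$income_gradient,
    rr_natural = x$config$rr_truth$natural,
    rr_unnatural = x$config$rr_truth$unnatural,
    seed = x$config$seed
  )
}

#' Global summary of an attribution result
#'
#' @param x an `mh_attribution` tibble.
#' @param ... unused.
#' @return one row per approach x measure with global attributable totals
#'   (and bound totals when present).
#' @method glance mh_attribution
#' @export
glance.mh_attribution <- function(x, ...) {
  has_bounds <- all(c("lower", "upper") %in% names(x))
  x %>%
    group_by(.data$approach, .data$measure) %>%
    summarise(
      n_locations = dplyr::n_distinct(.data$location),
      attributable = sum(.data$attributable),
      lower = if (has_bounds) sum(.data$lower) else NA_real_,
      upper = if (has_bounds) sum(.data$upper) else NA_real_,
      .groups = "drop"
    )
}

#' Global summary of a valuation
#'
#' @param x an `mh_valuation` tibble.
#' @param ... unused.
#' @return one row per approach x scheme with total value and DALYs.
#' @method glance mh_valuation
#' @export
glance.mh_valuation <- function(x, ...) {
  x %>%
    group_by(.data$approach, .data$scheme, .data$unit) %>%
    summarise(
      attributable_dalys = sum(.data$attributable_dalys),
      value_usd = sum(.data$value_usd),
      .groups = "drop"
    )
}

#' @export
print.mh_world <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mh_world> %d countries in %d regions (seed %d)\n  total DALYs %.3g, mean any-disorder prevalence %.3f\n  planted RR natural %.2f / unnatural %.2f, income gradient %.1f\n",
    g$n_countries, g$n_regions, g$seed, g$total_dalys, g$mean_prevalence,
    g$rr_natural, g$rr_unnatural, g$income_gradient
  ))
  invisible(x)
}
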