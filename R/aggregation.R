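#' Aggregate country attribution results to groups
#'
#' Sums attributable burden over GBD regions, World Bank income groups, or
#' the globe. Group shares are computed against the group's total all-cause
#' burden, and rates per 100,000 against the group's population, when the
#' corresponding tables are supplied. The global aggregate is computed by
#' summing the regional aggregates — every country belongs to exactly one
#' region, so regional totals sum to the global total to the bit.
#'
#' Countries without a World Bank income classification contribute to the
#' regional and global totals but not to any income-group total, so
#' income-group totals need not sum to the global figure.
#'
#' @param results an `mh_attribution` tibble (with or without bound
#'   columns).
#' @param locations location map with `location`, `gbd_region`,
#'   `income_group`.
#' @param grouping `"gbd_region"`, `"income_group"` or `"global"`.
#' @param burden optional canonical burden tibble used for the share-of-
#'   total-burden columns (its all-cause rows).
#' @param population optional tibble `location`, `population` for rate
#'   views.
#' @param config configuration (names the all-cause aggregate).
#' @return tibble with `group`, `approach`, `measure`, `attributable`,
#'   `lower`/`upper` (if present), and where computable `total_burden`,
#'   `share_pct`, `population`, `rate_per_100k`.
#' @export
aggregate_attribution <- function(results, locations,
                                  grouping = c("gbd_region", "income_group", "global"),
                                  burden = NULL, population = NULL,
                                  config = default_config()) {
  grouping <- match.arg(grouping)
  if (grouping == "global") {
    regional <- aggregate_attribution(results, locations, "gbd_region",
                                      burden = burden, population = population,
                                      config = config)
    out <- regional %>%
      group_by(.data$approach, .data$measure) %>%
      summarise(
        across(all_of(intersect(c("attributable", "lower", "upper",
                                  "total_burden", "population"),
                                names(regional))), sum),
        .groups = "drop"
      ) %>%
      mutate(group = "Global", .before = 1)
    return(finalize_aggregate(out))
  }

  lab <- locations %>% select("location", group = all_of(grouping))
  x <- results %>% left_join(lab, by = "location")
  if (grouping == "gbd_region" && anyNA(x$group)) {
    abort(sprintf("Country(ies) without a GBD region label: %s",
                  paste(unique(x$location[is.na(x$group)]), collapse = ", ")))
  }
  if (grouping == "income_group") {
    x <- x %>% filter(!is.na(.data$group) & .data$group != "Unclassified")
  }
  have_bounds <- all(c("lower", "upper") %in% names(x))
  out <- x %>%
    arrange(.data$group, .data$location) %>%
    group_by(.data$group, .data$approach, .data$measure) %>%
    summarise(
      attributable = sum(.data$attributable),
      lower = if (have_bounds) sum(.data$lower) else NA_real_,
      upper = if (have_bounds) sum(.data$upper) else NA_real_,
      .groups = "drop"
    )
  if (!have_bounds) out$lower <- out$upper <- NULL

  if (!is.null(burden)) {
    totals <- burden %>%
      filter(.data$cause == config$causes$all_cause, .data$metric == "count") %>%
      left_join(lab, by = "location") %>%
      filter(!is.na(.data$group),
             grouping != "income_group" | .data$group != "Unclassified") %>%
      arrange(.data$group, .data$location) %>%
      group_by(.data$group, .data$measure) %>%
      summarise(total_burden = sum(.data$val), .groups = "drop")
    out <- out %>% left_join(totals, by = c("group", "measure"))
  }
  if (!is.null(population)) {
    pops <- population %>%
      select("location", "population") %>%
      distinct() %>%
      left_join(lab, by = "location") %>%
      filter(!is.na(.data$group)) %>%
      arrange(.data$group, .data$location) %>%
      group_by(.data$group) %>%
      summarise(population = sum(.data$population), .groups = "drop")
    out <- out %>% left_join(pops, by = "group")
  }
  finalize_aggregate(out)
}

finalize_aggregate <- function(out) {
  if ("total_burden" %in% names(out)) {
    out$share_pct <- 100 * out$attributable / out$total_burden
  }
  if ("population" %in% names(out)) {
    out$rate_per_100k <- 1e5 * out$attributable / out$population
  }
  out
}

#' Assemble report tables
#'
#' Formats upstream results the way burden-of-disease reports present them:
#' a DALY table in millions with shares of total burden by income group, GBD
#' region and globally under each approach (with bounds), an economic-value
#' table in trillions per valuation scheme, and a percent-of-GDP table per
#' region. Rounding (one decimal for DALY millions and percents, two for
#' trillions) happens only here; all stored values upstream keep full
#' precision.
#'
#' @param results bounded `mh_attribution` results covering the approaches
#'   to report (missing approaches yield `NA` columns, not an error).
#' @param valuations a list of `mh_valuation` tibbles (one per scheme), or a
#'   single one.
#' @param locations location map.
#' @param burden canonical burden tibble (for shares).
#' @param econ economic table (for percent of GDP).
#' @param config configuration.
#' @return a list of class `mh_report` with elements `dalys`,
#'   `economic_value`, `pct_gdp`.
#' @export
make_report <- function(results, valuations, locations, burden, econ,
                        config = default_config()) {
  if (inherits(valuations, "mh_valuation")) valuations <- list(valuations)

  groupings <- list(
    global = "global", income = "income_group", region = "gbd_region"
  )
  daly_blocks <- purrr::map(groupings, function(g) {
    aggregate_attribution(results, locations, g, burden = burden,
                          config = config) %>%
      filter(.data$measure == "DALYs")
  })
  daly_tab <- bind_rows(daly_blocks, .id = "grouping_type") %>%
    mutate(
      dalys_millions = round(.data$attributable / 1e6, 1),
      dalys_millions_lower = round(.data$lower / 1e6, 1),
      dalys_millions_upper = round(.data$upper / 1e6, 1),
      share_pct = round(.data$share_pct, 1)
    ) %>%
    select("grouping_type", "group", "approach", "dalys_millions",
           "dalys_millions_lower", "dalys_millions_upper", "share_pct") %>%
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("grouping_type", "group"))),
      approach = approach_levels
    )

  econ_tab <- purrr::map(valuations, function(v) {
    percent_of_gdp(v, econ, locations, "global")
  }) %>%
    bind_rows() %>%
    mutate(
      value_trillions = round(.data$value_usd / 1e12, 2),
      value_trillions_lower = round(.data$lower / 1e12, 2),
      value_trillions_upper = round(.data$upper / 1e12, 2)
    ) %>%
    select("scheme", "approach", "value_trillions", "value_trillions_lower",
           "value_trillions_upper")

  base_scheme <- valuations[[1]]
  pct_tab <- percent_of_gdp(base_scheme, econ, locations, "gbd_region") %>%
    mutate(pct_gdp = round(.data$pct_gdp, 1)) %>%
    select("group", "approach", "scheme", "pct_gdp")

  structure(
    list(dalys = daly_tab, economic_value = econ_tab, pct_gdp = pct_tab),
    class = "mh_report"
  )
}

#' @export
print.mh_report <- function(x, ...) {
  cat("Attributable DALYs (millions) and share of total burden:\n")
  print(as.data.frame(x$dalys), row.names = FALSE)
  cat("\nEconomic value (trillions):\n")
  print(as.data.frame(x$economic_value), row.names = FALSE)
  cat("\nPercent of GDP by region (base scheme):\n")
  print(as.data.frame(x$pct_gdp), row.names = FALSE)
  invisible(x)
}
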