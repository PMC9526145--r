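#' Value-per-DALY scheme
#'
#' A scheme assigns a monetary value to one DALY: a multiple of GDP per
#' capita (1x as the base case, 3x as the high case), a fixed USD amount
#' (1,000 and 5,000 are the conventional low/high values), or a multiple of
#' PPP-adjusted GDP per capita (reported in international dollars).
#'
#' @param kind `"gdp_multiple"`, `"fixed_usd"` or `"gdp_multiple_ppp"`.
#' @param multiplier GDP-per-capita multiplier (> 0), used by the
#'   `gdp_multiple*` kinds.
#' @param fixed_value USD per DALY, used by `fixed_usd`.
#' @return a list with class `mh_scheme` (elements `kind`, `multiplier`,
#'   `fixed_value`, `label`, `unit`).
#' @export
#' @examples
#' valuation_scheme("gdp_multiple", multiplier = 3)
#' valuation_scheme("fixed_usd", fixed_value = 1000)
valuation_scheme <- function(kind = c("gdp_multiple", "fixed_usd", "gdp_multiple_ppp"),
                             multiplier = 1, fixed_value = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed_usd") {
    if (is.null(fixed_value) || fixed_value <= 0) {
      abort("`fixed_usd` schemes need a positive `fixed_value`.")
    }
    multiplier <- NULL
  } else {
    if (is.null(multiplier) || multiplier <= 0) {
      abort("GDP-multiple schemes need a positive `multiplier`.")
    }
    fixed_value <- NULL
  }
  label <- switch(kind,
    gdp_multiple = sprintf("%gx GDP per capita", multiplier),
    gdp_multiple_ppp = sprintf("%gx GDP per capita (PPP)", multiplier),
    fixed_usd = sprintf("USD %g per DALY", fixed_value)
  )
  structure(
    list(kind = kind, multiplier = multiplier, fixed_value = fixed_value,
         label = label,
         unit = if (kind == "gdp_multiple_ppp") "international dollars" else "USD"),
    class = "mh_scheme"
  )
}

#' Monetary value of attributable DALYs
#'
#' Values each country's attributable DALYs under a value-per-DALY scheme:
#' `DALYs x multiplier x GDP per capita` (or `x fixed value`). Bounds, when
#' present on the attribution table, are valued from the bound DALYs with
#' the same per-DALY value. The results are framed as the economic value of
#' welfare losses, not as losses of GDP itself. Countries without an
#' economic record are excluded with a warning (listed in the `excluded`
#' attribute). The input attribution table is never modified.
#'
#' @param attrib an `mh_attribution` tibble; only its DALY rows are valued.
#' @param econ economic tibble with `location`, `gdp_pc`, `gdp_ppp_pc` (see
#'   [read_econ_table()]); for harmonized sets pass `set$econ`.
#' @param scheme an [valuation_scheme()] object.
#' @return tibble of class `mh_valuation` with columns `location`, `iso3`,
#'   `approach`, `scheme`, `unit`, `attributable_dalys`, `value_usd`,
#'   `lower`, `upper`.
#' @export
value_burden <- function(attrib, econ, scheme = valuation_scheme()) {
  stopifnot(inherits(scheme, "mh_scheme"))
  dalys <- attrib %>% filter(.data$measure == "DALYs")
  if (nrow(dalys) == 0) abort("No DALY rows in the attribution table.")
  if (!"lower" %in% names(dalys)) dalys$lower <- NA_real_
  if (!"upper" %in% names(dalys)) dalys$upper <- NA_real_
  e <- econ %>% select("location", "gdp_pc", "gdp_ppp_pc") %>% distinct()
  joined <- dalys %>% left_join(e, by = "location")
  no_econ <- is.na(joined$gdp_pc) & scheme$kind != "fixed_usd"
  excluded <- unique(joined$location[no_econ])
  if (length(excluded) > 0) {
    warn(sprintf("Excluding %d location(s) without economic data from valuation: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
    joined <- joined[!no_econ, , drop = FALSE]
  }
# every value is multiplier x base, with the base the DALY x GDP-per-capita
  # product (or the DALYs themselves for fixed-USD schemes) and the multiplier
  # applied as the outermost operation at every aggregation level, so the 3x
  # scheme is bitwise 3x the 1x scheme (exact proportionality, country or group)
  base_of <- function(d) {
    switch(scheme$kind,
      gdp_multiple = d * joined$gdp_pc,
      gdp_multiple_ppp = d * joined$gdp_ppp_pc,
      fixed_usd = d
    )
  }
  mult <- scheme$multiplier %||% scheme$fixed_value
  scheme_label <- scheme$label
  scheme_unit <- scheme$unit
  out <- tibble(
    location = joined$location,
    iso3 = joined$iso3,
    approach = joined$approach,
    scheme = scheme_label,
    unit = scheme_unit,
    multiplier = mult,
    attributable_dalys = joined$attributable,
    base_value = base_of(joined$attributable),
    base_lower = base_of(joined$lower),
    base_upper = base_of(joined$upper),
    value_usd = mult * base_of(joined$attributable),
    lower = mult * base_of(joined$lower),
    upper = mult * base_of(joined$upper)
  )
  attr(out, "excluded") <- excluded
  class(out) <- c("mh_valuation", class(out))
  out
}

#' Economic value as a percent of GDP
#'
#' Aggregates country-level valuations to a grouping and expresses the group
#' value relative to the group's GDP: `100 x sum(value) / sum(gdp)` over the
#' member countries (group GDP is the member-country sum, not an external
#' aggregate).
#'
#' @param values an `mh_valuation` tibble from [value_burden()].
#' @param econ economic tibble with `location`, `gdp_usd`.
#' @param locations location map with `location` and the grouping column.
#' @param grouping `"gbd_region"`, `"income_group"` or `"global"`.
#' @return tibble with `group`, `approach`, `scheme`, `value_usd`, `lower`,
#'   `upper`, `gdp_usd`, `pct_gdp`.
#' @export
percent_of_gdp <- function(values, econ,
                           locations = NULL,
                           grouping = c("gbd_region", "income_group", "global")) {
  grouping <- match.arg(grouping)
  e <- econ %>% select("location", "gdp_usd") %>% distinct()
  x <- values %>% inner_join(e, by = "location")
  if (grouping == "global") {
    x$group <- "Global"
  } else {
    if (is.null(locations)) abort("`locations` is required for non-global groupings.")
    x <- x %>%
      left_join(select(locations, "location", group = all_of(grouping)),
                by = "location")
    if (grouping == "income_group") {
      x <- x %>% filter(!is.na(.data$group) & .data$group != "Unclassified")
    }
  }
  # multiplier applied outside the sum: group values stay exact multiples
  out <- x %>%
    group_by(.data$group, .data$approach, .data$scheme) %>%
    summarise(
      value_usd = .data$multiplier[1] * sum(.data$base_value),
      lower = .data$multiplier[1] * sum(.data$base_lower),
      upper = .data$multiplier[1] * sum(.data$base_upper),
      gdp_usd = sum(.data$gdp_usd),
      .groups = "drop"
    )
  if (any(out$gdp_usd <= 0)) {
    abort(sprintf("Zero group GDP for group(s): %s",
                  paste(out$group[out$gdp_usd <= 0], collapse = ", ")))
  }
  out %>% mutate(pct_gdp = 100 * .data$value_usd / .data$gdp_usd)
}
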