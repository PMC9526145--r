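canonical_measures <- c("DALYs", "YLLs", "YLDs", "Deaths", "Prevalence")
canonical_metrics <- c("count", "rate", "proportion")

measure_name_map <- c(
  "DALYs (Disability-Adjusted Life Years)" = "DALYs",
  "YLLs (Years of Life Lost)" = "YLLs",
  "YLDs (Years Lived with Disability)" = "YLDs",
  "DALYs" = "DALYs", "YLLs" = "YLLs", "YLDs" = "YLDs",
  "Deaths" = "Deaths", "Prevalence" = "Prevalence"
)
# stable public GHDx codes
measure_id_map <- c("1" = "Deaths", "2" = "DALYs", "3" = "YLDs",
                    "4" = "YLLs", "5" = "Prevalence")
metric_name_map <- c("Number" = "count", "Rate" = "rate",
                     "Percent" = "proportion", "Proportion" = "proportion")
metric_id_map <- c("1" = "count", "2" = "proportion", "3" = "rate")
metric_id_to_label <- c("1" = "Number", "2" = "Percent", "3" = "Rate")

#' Read a GBD-style burden extract
#'
#' Reads a long-format results CSV in either of the two common GHDx export
#' dialects — name-based (`measure_name`, `location_name`, `cause_name`,
#' `metric_name`) or id-based (`measure_id`, `location_id`, `cause_id`,
#' `metric_id`) — validates every row, and returns the canonical burden
#' table. Measure and metric ids are decoded with the stable public codes;
#' location and cause ids need a `lookup` because the full cause registry is
#' an external resource.
#'
#' Rows for age/sex strata other than all-ages/both-sexes are rejected (with
#' a message); the attributes `rows_in`, `rows_kept` and `rows_rejected`
#' account for every input row. If a `population` table is supplied, rows in
#' the rate metric (per 100,000) are converted to counts, the pipeline's
#' canonical metric.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (detect by header), `"name"`, or `"id"`.
#' @param lookup for the id dialect, a list with tibbles `locations`
#'   (`location_id`, `location_name`) and `causes` (`cause_id`,
#'   `cause_name`).
#' @param population optional tibble `location`, `population` used to convert
#'   rates to counts.
#' @return tibble with columns `measure`, `location`, `cause`, `cause_level`,
#'   `metric`, `year`, `val`, `lower`, `upper`.
#' @export
read_burden_table <- function(path, dialect = c("auto", "name", "id"),
                              lookup = NULL, population = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "auto") {
    dialect <- if ("measure_name" %in% names(raw)) "name"
    else if ("measure_id" %in% names(raw)) "id"
    else abort("Cannot detect dialect: neither `measure_name` nor `measure_id` present.")
  }
  need <- if (dialect == "name") {
    c("measure_name", "location_name", "cause_name", "metric_name",
      "year", "val", "upper", "lower")
  } else {
    c("measure_id", "location_id", "cause_id", "metric_id",
      "year", "val", "upper", "lower")
  }
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }

  rows_in <- nrow(raw)
  raw$.row <- seq_len(rows_in)

  if (dialect == "id") {
    if (is.null(lookup) || is.null(lookup$locations) || is.null(lookup$causes)) {
      abort("The id dialect needs `lookup` with `locations` and `causes` tables.")
    }
    raw <- raw %>%
      mutate(
        measure_name = unname(measure_id_map[as.character(.data$measure_id)]),
        metric_name = unname(metric_id_to_label[as.character(.data$metric_id)])
      ) %>%
      left_join(rename(lookup$locations, location_name = "location_name"),
                by = "location_id") %>%
      left_join(rename(lookup$causes, cause_name = "cause_name"),
                by = "cause_id")
    if (anyNA(raw$location_name) || anyNA(raw$cause_name)) {
      abort("Lookup tables do not cover all location_id/cause_id values.")
    }
  }

  # keep only all-ages, both-sexes strata if stratified columns are present
  rejected <- 0L
  for (col in c("age_name", "sex_name")) {
    if (col %in% names(raw)) {
      ok_vals <- if (col == "age_name") c("All ages", "All Ages") else c("Both", "Both sexes")
      drop <- !(raw[[col]] %in% ok_vals)
      if (any(drop)) {
        inform(sprintf("Rejecting %d row(s) outside the all-ages/both-sexes stratum (%s).",
                       sum(drop), col))
        rejected <- rejected + sum(drop)
        raw <- raw[!drop, , drop = FALSE]
      }
    }
  }

  unknown_measure <- setdiff(unique(raw$measure_name), names(measure_name_map))
  if (length(unknown_measure) > 0) {
    abort(sprintf("Unknown measure label(s): %s",
                  paste(unknown_measure, collapse = ", ")))
  }
  unknown_metric <- setdiff(unique(raw$metric_name), names(metric_name_map))
  if (length(unknown_metric) > 0) {
    abort(sprintf("Unknown metric label(s): %s",
                  paste(unknown_metric, collapse = ", ")))
  }

  out <- tibble(
    measure = unname(measure_name_map[raw$measure_name]),
    location = raw$location_name,
    cause = raw$cause_name,
    cause_level = if ("cause_level" %in% names(raw)) as.integer(raw$cause_level) else NA_integer_,
    metric = unname(metric_name_map[raw$metric_name]),
    year = as.integer(raw$year),
    val = as.numeric(raw$val),
    lower = as.numeric(raw$lower),
    upper = as.numeric(raw$upper),
    .row = raw$.row
  )
  validate_burden(out)
  out$.row <- NULL
  attr(out, "rows_in") <- rows_in
  attr(out, "rows_kept") <- nrow(out)
  attr(out, "rows_rejected") <- rejected
  if (!is.null(population)) {
    out <- convert_burden_metric(out, to = "count", population = population)
  }
  out
}

validate_burden <- function(x) {
  rows <- if (".row" %in% names(x)) x$.row else seq_len(nrow(x))
  bad <- which(x$val < 0 | x$lower < 0 | x$upper < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative burden value(s) at row(s): %s",
                  paste(utils::head(rows[bad], 10), collapse = ", ")))
  }
  bad <- which(!(x$lower <= x$val & x$val <= x$upper))
  if (length(bad) > 0) {
    abort(sprintf("Interval violation (need lower <= val <= upper) at row(s): %s",
                  paste(utils::head(rows[bad], 10), collapse = ", ")))
  }
  prop <- which(x$metric == "proportion")
  bad <- prop[x$val[prop] > 1 | x$upper[prop] > 1]
  if (length(bad) > 0) {
    abort(sprintf("Proportion outside [0, 1] at row(s): %s",
                  paste(utils::head(rows[bad], 10), collapse = ", ")))
  }
  invisible(x)
}

#' Convert burden rows between counts and rates
#'
#' Converts between the count metric and the rate-per-100,000 metric using a
#' population table. Proportion rows (prevalence) pass through unchanged.
#' Conversion composed with its inverse is the identity to floating-point
#' precision.
#'
#' @param burden canonical burden tibble.
#' @param to `"count"` or `"rate"`.
#' @param population tibble with `location`, `population`.
#' @return the converted tibble.
#' @export
convert_burden_metric <- function(burden, to = c("count", "rate"), population) {
  to <- match.arg(to)
  from <- if (to == "count") "rate" else "count"
  idx <- burden$metric == from
  if (!any(idx)) return(burden)
  pop <- population %>% select("location", "population") %>% distinct()
  joined <- burden[idx, ] %>% left_join(pop, by = "location")
  if (anyNA(joined$population) || any(joined$population <= 0)) {
    abort(sprintf(
      "Missing or non-positive population for location(s): %s",
      paste(unique(joined$location[is.na(joined$population) | joined$population <= 0]),
            collapse = ", ")
    ))
  }
  f <- if (to == "count") joined$population / 1e5 else 1e5 / joined$population
  burden[idx, c("val", "lower", "upper")] <-
    joined[, c("val", "lower", "upper")] * f
  burden$metric[idx] <- to
  burden
}

#' Write the canonical burden table
#'
#' Serializes a burden table as CSV with the fixed canonical column order.
#' A table written and re-read (with [read_canonical_burden()]) is
#' value-identical.
#'
#' @param burden canonical burden tibble (an `iso3` column is written if
#'   present, else left empty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(burden, path) {
  out <- burden
  if (!"iso3" %in% names(out)) out$iso3 <- NA_character_
  out <- out[, c("measure", "location", "iso3", "cause", "cause_level",
                 "metric", "year", "val", "lower", "upper")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a canonical burden table written by [write_burden_table()]
#' @param path CSV path.
#' @return canonical burden tibble.
#' @export
read_canonical_burden <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         iso3 = readr::col_character(),
                         cause_level = readr::col_integer()
                       ))
  validate_burden(x)
  as_tibble(x)
}

#' Read a World Bank style GDP table
#'
#' Reads GDP in current USD (and optionally PPP international dollars) from
#' either a long table with columns `location`, `year`, `gdp_usd`
#' (optionally `gdp_ppp`, `iso3`) or a WDI-style wide export with
#' `Country Name`, `Country Code`, `Indicator Code` and one column per year
#' (indicator codes `NY.GDP.MKTP.CD` and `NY.GDP.MKTP.PP.CD`).
#'
#' Per-capita values are computed with the supplied (GBD-style) population
#' table, not any population column in the file, for consistency with the
#' epidemiological inputs. Locations with missing GDP, or absent from the
#' population table, are excluded with a warning (and recorded in the
#' `excluded` attribute); a matched population that is zero or missing is an
#' error.
#'
#' @param path CSV file path.
#' @param population tibble `location`, `population` (persons).
#' @param year analysis year to extract.
#' @return tibble `location`, `iso3`, `year`, `gdp_usd`, `gdp_ppp`,
#'   `population`, `gdp_pc`, `gdp_ppp_pc`.
#' @export
read_econ_table <- function(path, population, year = 2019) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("Indicator Code" %in% names(raw)) {
    ycol <- as.character(year)
    if (!ycol %in% names(raw)) {
      abort(sprintf("WDI table has no column for year %s.", year))
    }
    long <- raw %>%
      select(location = "Country Name", iso3 = "Country Code",
             indicator = "Indicator Code", value = all_of(ycol)) %>%
      filter(.data$indicator %in% c("NY.GDP.MKTP.CD", "NY.GDP.MKTP.PP.CD")) %>%
      mutate(indicator = ifelse(.data$indicator == "NY.GDP.MKTP.CD",
                                "gdp_usd", "gdp_ppp")) %>%
      tidyr::pivot_wider(names_from = "indicator", values_from = "value")
    econ <- long %>% mutate(year = as.integer(!!year))
  } else {
    need <- c("location", "year", "gdp_usd")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf("Missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    econ <- raw %>% filter(.data$year == !!year)
    if (!"iso3" %in% names(econ)) econ$iso3 <- NA_character_
    if (!"gdp_ppp" %in% names(econ)) econ$gdp_ppp <- NA_real_
  }

  excluded <- character(0)
  no_gdp <- is.na(econ$gdp_usd)
  if (any(no_gdp)) {
    excluded <- c(excluded, econ$location[no_gdp])
    warn(sprintf("Excluding %d location(s) with missing GDP: %s",
                 sum(no_gdp), paste(econ$location[no_gdp], collapse = ", ")))
    econ <- econ[!no_gdp, , drop = FALSE]
  }
  pop <- population %>% select("location", "population") %>% distinct()
  joined <- econ %>% left_join(pop, by = "location")
  no_pop <- is.na(joined$population) & !(joined$location %in% pop$location)
  if (any(no_pop)) {
    excluded <- c(excluded, joined$location[no_pop])
    warn(sprintf("Excluding %d location(s) absent from the population table: %s",
                 sum(no_pop), paste(joined$location[no_pop], collapse = ", ")))
    joined <- joined[!no_pop, , drop = FALSE]
  }
  if (any(is.na(joined$population) | joined$population <= 0)) {
    abort(sprintf("Zero or missing population for location(s): %s",
                  paste(joined$location[is.na(joined$population) | joined$population <= 0],
                        collapse = ", ")))
  }
  out <- joined %>%
    mutate(
      gdp_pc = .data$gdp_usd / .data$population,
      gdp_ppp_pc = .data$gdp_ppp / .data$population
    ) %>%
    select("location", "iso3", "year", "gdp_usd", "gdp_ppp",
           "population", "gdp_pc", "gdp_ppp_pc")
  attr(out, "excluded") <- unique(excluded)
  out
}

#' Built-in location-name alias table
#'
#' Country names diverge between GBD and World Bank publications
#' ("Viet Nam" vs "Vietnam", "Russian Federation" vs "Russia", ...). The
#' shipped alias table maps common variants to ISO-3166 alpha-3 codes so
#' [harmonize_locations()] can join on iso3 when names disagree. Users can
#' extend it by passing their own table with columns `alias`, `iso3`.
#'
#' @return tibble with columns `alias`, `iso3`.
#' @export
location_aliases <- function() {
  path <- system.file("extdata", "location_aliases.csv", package = "mhburden")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Harmonize burden, economic and location tables
#'
#' Joins region and income-group labels onto the burden and economic tables.
#' Burden locations must all resolve against the location map (directly by
#' name, or through the alias table by iso3) — an unmapped burden location is
#' a hard error. Economic rows that do not resolve (e.g. aggregates such as
#' "World") are dropped with a warning and reported in the
#' `unmatched_econ` attribute.
#'
#' @param burden canonical burden tibble.
#' @param econ economic tibble from [read_econ_table()].
#' @param map location map tibble with `location`, `iso3`, `gbd_region`,
#'   `income_group`.
#' @param aliases alias tibble (`alias`, `iso3`); defaults to the shipped
#'   table.
#' @return a list with class `mh_analysis_set`: elements `burden`, `econ`
#'   (both carrying `iso3`, `gbd_region`, `income_group`) and `locations`.
#' @export
harmonize_locations <- function(burden, econ, map, aliases = location_aliases()) {
  resolve <- function(loc) {
    iso <- map$iso3[match(loc, map$location)]
    unresolved <- is.na(iso)
    if (any(unresolved) && !is.null(aliases) && nrow(aliases) > 0) {
      iso[unresolved] <- aliases$iso3[match(loc[unresolved], aliases$alias)]
    }
    iso
  }
  keys <- map %>% select("iso3", canonical_location = "location",
                         "gbd_region", "income_group")

  b_iso <- resolve(burden$location)
  if (anyNA(b_iso)) {
    abort(sprintf("Burden locations with no entry in the location map: %s",
                  paste(sort(unique(burden$location[is.na(b_iso)])), collapse = ", ")))
  }
  burden2 <- burden %>%
    mutate(iso3 = b_iso) %>%
    left_join(keys, by = "iso3") %>%
    mutate(location = .data$canonical_location) %>%
    select(-"canonical_location")

  e_iso <- resolve(econ$location)
  unmatched <- unique(econ$location[is.na(e_iso)])
  if (length(unmatched) > 0) {
    warn(sprintf("Dropping %d economic location(s) not in the location map: %s",
                 length(unmatched), paste(unmatched, collapse = ", ")))
  }
  econ2 <- econ[!is.na(e_iso), , drop = FALSE] %>%
    mutate(iso3 = e_iso[!is.na(e_iso)]) %>%
    left_join(keys, by = "iso3") %>%
    mutate(location = .data$canonical_location) %>%
    select(-"canonical_location")

  out <- structure(
    list(burden = burden2, econ = econ2, locations = as_tibble(map)),
    class = "mh_analysis_set"
  )
  attr(out, "unmatched_econ") <- unmatched
  out
}
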