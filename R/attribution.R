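sum_by_location <- function(burden, measure, causes, value_col, locs) {
  s <- burden %>%
    filter(.data$measure == !!measure, .data$metric == "count",
           .data$cause %in% causes) %>%
    group_by(.data$location) %>%
    summarise(x = sum(.data[[value_col]]), .groups = "drop")
  out <- s$x[match(locs, s$location)]
  out[is.na(out)] <- 0
  out
}

new_attribution <- function(location, approach, measure, direct, msk,
                            paf_natural, paf_unnatural) {
  tibble(
    location = location,
    approach = approach,
    measure = measure,
    component_direct = direct,
    component_msk = msk,
    component_paf_natural = paf_natural,
    component_paf_unnatural = paf_unnatural,
    attributable = ((direct + msk) + paf_natural) + paf_unnatural
  )
}

#' Attribute burden to mental disorders under an estimation approach
#'
#' The workhorse of the pipeline. For each location and measure it computes
#' the burden attributable to mental disorders under one of three approaches:
#'
#' * `original` — the conventional hierarchical allocation: the full burden
#'   of the core mental-disorder causes only.
#' * `reallocation` — the expanded morbidity allocation: core mental
#'   disorders plus substance-use and neurological disorders, the configured
#'   fraction (default one third) of the chronic-pain musculoskeletal
#'   causes, and the full burden of self-harm, for every measure.
#' * `composite` — morbidity (YLDs) as under reallocation but without
#'   self-harm; mortality (YLLs, deaths) as the direct mortality of those
#'   same causes plus premature mortality attributed through the PAF:
#'   the natural-cause PAF applied to the NCD base net of the directly
#'   attributed causes, and the unnatural-cause PAF applied to the injuries
#'   base (which contains self-harm). DALYs are the sum of the YLL and YLD
#'   results.
#'
#' Attributable DALYs are composed as YLL + YLD whenever both measures are
#' present (exactly, so DALY additivity holds to the bit); a burden table
#' carrying only DALY records still works for the two morbidity-reallocation
#' approaches. Each result row records its component breakdown
#' (`component_direct`, `component_msk`, `component_paf_natural`,
#' `component_paf_unnatural`) whose sum is the attributable total.
#'
#' @param burden canonical burden tibble in counts (see
#'   [read_burden_table()] / [generate_world()]).
#' @param approach `"original"`, `"reallocation"` or `"composite"`.
#' @param config an `mh_config` list.
#' @param value_col burden value column to use (`"val"`, `"lower"`,
#'   `"upper"`); the sensitivity bounds re-run the engine on the interval
#'   columns.
#' @param msk_fraction override of the configured musculoskeletal-pain
#'   fraction.
#' @param rr_bound which end of the RR confidence interval to use
#'   (`"point"`, `"lower"`, `"upper"`); composite only.
#' @param prevalence_col prevalence column to use; defaults to `value_col`.
#' @param prevalence_mode passed to [country_prevalence()].
#' @return a tibble of class `mh_attribution` with columns `location`,
#'   `approach`, `measure`, `component_direct`, `component_msk`,
#'   `component_paf_natural`, `component_paf_unnatural`, `attributable`.
#' @export
#' @examples
#' w <- generate_world(world_config(n_countries = 4, seed = 1))
#' run_approach(w$burden, "composite")
run_approach <- function(burden,
                         approach = c("original", "reallocation", "composite"),
                         config = default_config(),
                         value_col = "val",
                         msk_fraction = NULL,
                         rr_bound = c("point", "lower", "upper"),
                         prevalence_col = value_col,
                         prevalence_mode = "any_disorder") {
  approach <- match.arg(approach)
  rr_bound <- match.arg(rr_bound)
  msk_fraction <- msk_fraction %||% config$msk_fraction
  cz <- config$causes
  counts <- filter(burden, .data$metric == "count")
  locs <- sort(unique(counts$location))
  if (length(locs) == 0) abort("No count-metric burden rows to attribute.")
  measures_present <- intersect(c("YLDs", "YLLs", "Deaths", "DALYs"),
                                unique(counts$measure))

  if (approach %in% c("original", "reallocation")) {
    direct_set <- direct_causes(config, approach)
    use_msk <- approach == "reallocation"
    per_measure <- function(ms) {
      new_attribution(
        locs, approach, ms,
        direct = sum_by_location(counts, ms, direct_set, value_col, locs),
        msk = if (use_msk) {
          msk_fraction * sum_by_location(counts, ms, cz$musculoskeletal_pain,
                                         value_col, locs)
        } else {
          rep(0, length(locs))
        },
        paf_natural = rep(0, length(locs)),
        paf_unnatural = rep(0, length(locs))
      )
    }
    base_measures <- intersect(c("YLDs", "YLLs", "Deaths"), measures_present)
    res <- purrr::map(base_measures, per_measure) %>% bind_rows()
    res <- add_daly_rows(res, counts, per_measure, measures_present)
    return(finish_attribution(res, burden, approach))
  }

  # composite
  for (ms in c("YLDs", "YLLs")) {
    if (!ms %in% measures_present) {
      abort(sprintf("The composite approach needs %s records in the burden table.", ms))
    }
  }
  rr <- config$rr
  pick <- function(x) x[[rr_bound]]
  if (pick(rr$natural) < 1 || pick(rr$unnatural) < 1) {
    abort("Protective relative risks (< 1) are outside the scope of this attribution; refusing to produce negative attribution.")
  }
  prev <- country_prevalence(burden, prevalence_mode, config, prevalence_col)
  paf <- tibble(
    location = prev$location,
    paf_natural = compute_paf(prev$prevalence, pick(rr$natural)),
    paf_unnatural = compute_paf(prev$prevalence, pick(rr$unnatural))
  )
  missing <- setdiff(locs, paf$location)
  if (length(missing) > 0) {
    abort(sprintf("No prevalence/PAF for location(s): %s",
                  paste(missing, collapse = ", ")))
  }
  paf <- paf[match(locs, paf$location), ]

  direct_set <- direct_causes(config, "composite")
  yld_direct_set <- if (isTRUE(config$composite_self_harm_yld)) {
    c(direct_set, cz$self_harm)
  } else {
    direct_set
  }
  yld <- new_attribution(
    locs, approach, "YLDs",
    direct = sum_by_location(counts, "YLDs", yld_direct_set, value_col, locs),
    msk = msk_fraction * sum_by_location(counts, "YLDs", cz$musculoskeletal_pain,
                                         value_col, locs),
    paf_natural = rep(0, length(locs)),
    paf_unnatural = rep(0, length(locs))
  )
  mortality_measure <- function(ms) {
    bases <- paf_mortality_base(counts, config, measure = ms,
                                value_col = value_col,
                                msk_fraction = msk_fraction)
    bases <- bases[match(locs, bases$location), ]
    new_attribution(
      locs, approach, ms,
      direct = sum_by_location(counts, ms, direct_set, value_col, locs),
      msk = msk_fraction * sum_by_location(counts, ms, cz$musculoskeletal_pain,
                                           value_col, locs),
      paf_natural = paf$paf_natural * bases$natural_base,
      paf_unnatural = paf$paf_unnatural * bases$unnatural_base
    )
  }
  res <- bind_rows(
    yld,
    mortality_measure("YLLs"),
    if ("Deaths" %in% measures_present) mortality_measure("Deaths")
  )
  res <- bind_rows(res, compose_daly(res))
  finish_attribution(res, burden, approach)
}

# DALY rows: compose from YLL + YLD when both exist (bitwise additivity),
# otherwise fall back to direct attribution of DALY records.
add_daly_rows <- function(res, counts, per_measure, measures_present) {
  if (all(c("YLDs", "YLLs") %in% measures_present)) {
    bind_rows(res, compose_daly(res))
  } else if ("DALYs" %in% measures_present) {
    bind_rows(res, per_measure("DALYs"))
  } else {
    res
  }
}

compose_daly <- function(res) {
  yll <- filter(res, .data$measure == "YLLs") %>% arrange(.data$location)
  yld <- filter(res, .data$measure == "YLDs") %>% arrange(.data$location)
  stopifnot(identical(yll$location, yld$location))
  tibble(
    location = yll$location,
    approach = yll$approach,
    measure = "DALYs",
    component_direct = yll$component_direct + yld$component_direct,
    component_msk = yll$component_msk + yld$component_msk,
    component_paf_natural = yll$component_paf_natural + yld$component_paf_natural,
    component_paf_unnatural = yll$component_paf_unnatural + yld$component_paf_unnatural,
    attributable = yll$attributable + yld$attributable
  )
}

finish_attribution <- function(res, burden, approach) {
  if ("iso3" %in% names(burden)) {
    key <- burden %>% distinct(.data$location, .data$iso3)
    res <- left_join(res, key, by = "location")
  } else {
    res$iso3 <- NA_character_
  }
  res <- res %>%
    select("location", "iso3", "approach", "measure", "component_direct",
           "component_msk", "component_paf_natural", "component_paf_unnatural",
           "attributable") %>%
    arrange(.data$measure, .data$location)
  class(res) <- c("mh_attribution", class(res))
  res
}

#' Run all three estimation approaches
#'
#' @inheritParams run_approach
#' @param ... passed on to [run_approach()].
#' @return an `mh_attribution` tibble stacking the three approaches.
#' @export
run_all_approaches <- function(burden, config = default_config(), ...) {
  res <- purrr::map(
    c("original", "reallocation", "composite"),
    function(a) run_approach(burden, a, config, ...)
  ) %>% bind_rows()
  class(res) <- c("mh_attribution", setdiff(class(res), "mh_attribution"))
  res
}
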