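#' Population attributable fraction (Levin's formula)
#'
#' Computes the fraction of an outcome attributable to an exposure from the
#' exposure prevalence `p` and the relative risk `RR`:
#' \deqn{PAF = \frac{p\,(RR - 1)}{1 + p\,(RR - 1)}.}
#' For `RR >= 1` the result lies in `[0, 1)`; a protective `RR < 1` yields a
#' negative fraction, which the attribution engine refuses (see
#' [run_approach()]). PAF is strictly increasing in both arguments when
#' `RR > 1`.
#'
#' @param prevalence exposure prevalence, proportion(s) in `[0, 1]`.
#' @param rr relative risk(s), `> 0`. Recycled against `prevalence`.
#' @return numeric vector of attributable fractions.
#' @export
#' @examples
#' compute_paf(0.15, 2.2) # 0.18 / 1.18
compute_paf <- function(prevalence, rr) {
  if (any(is.na(prevalence)) || any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` must lie in [0, 1].")
  }
  if (any(is.na(rr)) || any(rr <= 0)) {
    abort("`rr` must be > 0.")
  }
  excess <- prevalence * (rr - 1)
  excess / (1 + excess)
}

#' Per-country prevalence of any mental disorder
#'
#' Extracts the exposure prevalence used in the PAF from the burden table.
#' The default `any_disorder` mode reads the aggregate mental-disorders
#' cause's prevalence verbatim — appropriate when the relative risk contrasts
#' people with *any* disorder against those without, since summing
#' per-disorder fractions would double-count comorbid individuals. The
#' `complement_product` mode combines per-disorder prevalences as
#' `1 - prod(1 - p_d)`, which assumes disorders occur independently.
#'
#' @param burden canonical burden tibble containing prevalence rows
#'   (proportion metric).
#' @param mode `"any_disorder"` or `"complement_product"`.
#' @param config an `mh_config` list; `config$causes$prevalence_cause` names
#'   the aggregate cause, `config$causes$mental_core` the per-disorder set.
#' @param value_col `"val"`, `"lower"` or `"upper"`.
#' @return tibble with columns `location`, `prevalence`.
#' @export
country_prevalence <- function(burden,
                               mode = c("any_disorder", "complement_product"),
                               config = default_config(), value_col = "val") {
  mode <- match.arg(mode)
  prev <- burden %>%
    filter(.data$measure == "Prevalence", .data$metric == "proportion")
  all_locs <- sort(unique(burden$location[burden$measure != "Prevalence"]))
  if (length(all_locs) == 0) all_locs <- sort(unique(prev$location))
  if (mode == "any_disorder") {
    p <- prev %>%
      filter(.data$cause == config$causes$prevalence_cause) %>%
      group_by(.data$location) %>%
      summarise(prevalence = .data[[value_col]][1], .groups = "drop")
  } else {
    p <- prev %>%
      filter(.data$cause %in% config$causes$mental_core) %>%
      group_by(.data$location) %>%
      summarise(prevalence = 1 - prod(1 - .data[[value_col]]), .groups = "drop")
  }
  missing <- setdiff(all_locs, p$location)
  if (length(missing) > 0) {
    abort(sprintf("No prevalence available for location(s): %s",
                  paste(missing, collapse = ", ")))
  }
  p %>% filter(.data$location %in% all_locs) %>% arrange(.data$location)
}

#' PAF point estimates and bounds per country
#'
#' Convenience wrapper combining [country_prevalence()] with the configured
#' relative risks: point PAFs pair point prevalence with point RR, the lower
#' bound pairs lower prevalence with the lower end of the RR confidence
#' interval, and the upper bound the upper analogues (concordant extremes,
#' matching how the sensitivity analysis composes bounds).
#'
#' @inheritParams country_prevalence
#' @return tibble `location`, `paf_natural`, `paf_natural_lower`,
#'   `paf_natural_upper`, `paf_unnatural`, `paf_unnatural_lower`,
#'   `paf_unnatural_upper`.
#' @export
paf_estimates <- function(burden, config = default_config(),
                          mode = c("any_disorder", "complement_product")) {
  mode <- match.arg(mode)
  p <- country_prevalence(burden, mode, config, "val")
  p_lo <- country_prevalence(burden, mode, config, "lower")
  p_hi <- country_prevalence(burden, mode, config, "upper")
  rr <- config$rr
  tibble(
    location = p$location,
    paf_natural = compute_paf(p$prevalence, rr$natural$point),
    paf_natural_lower = compute_paf(p_lo$prevalence, rr$natural$lower),
    paf_natural_upper = compute_paf(p_hi$prevalence, rr$natural$upper),
    paf_unnatural = compute_paf(p$prevalence, rr$unnatural$point),
    paf_unnatural_lower = compute_paf(p_lo$prevalence, rr$unnatural$lower),
    paf_unnatural_upper = compute_paf(p_hi$prevalence, rr$unnatural$upper)
  )
}

#' Apply PAFs to mortality bases
#'
#' Multiplies the natural- and unnatural-cause PAFs by their respective
#' mortality bases (YLLs or deaths) and sums, per location. Attribution is
#' linear in the base.
#'
#' @param paf tibble with `location`, `paf_natural`, `paf_unnatural`.
#' @param bases tibble with `location`, `natural_base`, `unnatural_base`
#'   (non-negative counts, from [paf_mortality_base()]).
#' @return tibble `location`, `attributable_natural`,
#'   `attributable_unnatural`, `attributable` (their sum).
#' @export
attribute_mortality <- function(paf, bases) {
  if (any(bases$natural_base < 0) || any(bases$unnatural_base < 0)) {
    abort("Mortality bases must be non-negative.")
  }
  joined <- inner_join(paf, bases, by = "location")
  joined %>%
    mutate(
      attributable_natural = .data$paf_natural * .data$natural_base,
      attributable_unnatural = .data$paf_unnatural * .data$unnatural_base,
      attributable = .data$attributable_natural + .data$attributable_unnatural
    ) %>%
    select("location", "attributable_natural", "attributable_unnatural",
           "attributable")
}
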