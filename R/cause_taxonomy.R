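#' Default analysis configuration
#'
#' Builds the configuration list that drives the whole pipeline: the cause
#' taxonomy (which GBD causes count as mental-disorder burden under each
#' allocation approach), the musculoskeletal-pain reallocation fraction and
#' its sensitivity bounds, the relative-risk parameters used for the
#' population attributable fraction of mortality, and the analysis year.
#'
#' The default cause lists are a judgement call that users should review:
#' the chronic-pain / somatoform set (`musculoskeletal_pain`) is taken to be
#' the musculoskeletal causes without a clear anatomical correlate — low back
#' pain, neck pain, and other musculoskeletal disorders — because no
#' authoritative enumeration exists. All lists can be overridden via
#' arguments or a YAML file (see [read_config()]).
#'
#' The default relative risk applies the pooled all-cause mortality RR of 2.2
#' (95% CI 2.1–2.3) for people with mental disorders to both the natural-cause
#' and unnatural-cause mortality bases; runs under this default are labelled
#' `"all-cause RR approximation"`. Supply stratum-specific RRs through
#' [rr_config()] when they are available.
#'
#' @param causes optional named list overriding any of the cause sets
#'   (`mental_core`, `substance`, `neurological`, `musculoskeletal_pain`,
#'   `self_harm`, `ncd_root`, `injuries_root`, `all_cause`,
#'   `prevalence_cause`).
#' @param msk_fraction fraction of musculoskeletal-pain burden reallocated to
#'   mental disorders; default 1/3.
#' @param msk_fraction_bounds length-2 numeric, the lower/upper sensitivity
#'   bounds on `msk_fraction`; default `c(1/6, 1/2)`.
#' @param rr relative-risk block as produced by [rr_config()].
#' @param include_substance named logical vector saying whether substance-use
#'   disorders count as mental-disorder burden under each approach. The
#'   default mirrors current GBD practice (classified separately, hence
#'   excluded from the original allocation) while both expanded approaches
#'   include them.
#' @param composite_self_harm_yld logical; if `TRUE` the composite approach
#'   also takes the full self-harm YLDs. Default `FALSE`: self-harm enters
#'   the composite estimate only through the unnatural-mortality PAF.
#' @param year analysis year (calendar year of the burden extract).
#'
#' @return a named list with class `mh_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$rr$natural$point
default_config <- function(causes = list(),
                           msk_fraction = 1 / 3,
                           msk_fraction_bounds = c(1 / 6, 1 / 2),
                           rr = rr_config(all_cause = list(point = 2.2, lower = 2.1, upper = 2.3)),
                           include_substance = c(original = FALSE, reallocation = TRUE, composite = TRUE),
                           composite_self_harm_yld = FALSE,
                           year = 2019) {
  base_causes <- list(
    mental_core = c(
      "Schizophrenia", "Depressive disorders", "Bipolar disorder",
      "Anxiety disorders", "Eating disorders", "Autism spectrum disorders",
      "Attention-deficit/hyperactivity disorder", "Conduct disorder",
      "Idiopathic developmental intellectual disability",
      "Other mental disorders"
    ),
    substance = c("Alcohol use disorders", "Drug use disorders"),
    neurological = c(
      "Alzheimer's disease and other dementias", "Parkinson's disease",
      "Idiopathic epilepsy", "Multiple sclerosis", "Motor neuron disease",
      "Headache disorders", "Other neurological disorders"
    ),
    musculoskeletal_pain = c(
      "Low back pain", "Neck pain", "Other musculoskeletal disorders"
    ),
    self_harm = "Self-harm",
    ncd_root = "Non-communicable diseases",
    injuries_root = "Injuries",
    all_cause = "All causes",
    prevalence_cause = "Mental disorders"
  )
  for (nm in names(causes)) base_causes[[nm]] <- causes[[nm]]

  cfg <- structure(
    list(
      causes = base_causes,
      msk_fraction = msk_fraction,
      msk_fraction_bounds = msk_fraction_bounds,
      rr = rr,
      include_substance = include_substance,
      composite_self_harm_yld = composite_self_harm_yld,
      year = year
    ),
    class = "mh_config"
  )
  validate_config(cfg)
  cfg
}

#' Relative-risk configuration for mortality attribution
#'
#' The PAF machinery needs relative risks of death for people with mental
#' disorders versus without, separately for natural causes (disease) and
#' unnatural causes (injuries including self-harm). There is no silent
#' default: either both strata are supplied, or a single pooled all-cause RR
#' is supplied and applied to both strata, in which case the configuration is
#' labelled an all-cause approximation.
#'
#' @param natural,unnatural lists `list(point =, lower =, upper =)` with the
#'   RR point estimate and 95% CI for the stratum.
#' @param all_cause pooled all-cause RR in the same form, used for both
#'   strata when stratum-specific values are not given.
#' @param provenance free-text note recording where the values come from.
#'
#' @return a list with elements `natural`, `unnatural`, `provenance`,
#'   `approximation` (logical).
#' @export
rr_config <- function(natural = NULL, unnatural = NULL, all_cause = NULL,
                      provenance = NULL) {
  check_rr <- function(x, what) {
    if (!is.list(x) || !all(c("point", "lower", "upper") %in% names(x))) {
      abort(sprintf("`%s` must be a list with elements point, lower, upper.", what))
    }
    if (any(unlist(x[c("point", "lower", "upper")]) <= 0)) {
      abort(sprintf("`%s` relative risks must be > 0.", what))
    }
    if (!(x$lower <= x$point && x$point <= x$upper)) {
      abort(sprintf("`%s` must satisfy lower <= point <= upper.", what))
    }
    x[c("point", "lower", "upper")]
  }
  if (is.null(natural) && is.null(unnatural)) {
    if (is.null(all_cause)) {
      abort(paste0(
        "Relative risks are required: supply `natural` and `unnatural`, ",
        "or a pooled `all_cause` RR to use for both strata."
      ))
    }
    ac <- check_rr(all_cause, "all_cause")
    return(list(
      natural = ac, unnatural = ac,
      provenance = provenance %||% "pooled all-cause RR applied to both strata",
      approximation = TRUE
    ))
  }
  if (is.null(natural) || is.null(unnatural)) {
    abort("Supply both `natural` and `unnatural`, or `all_cause` alone.")
  }
  list(
    natural = check_rr(natural, "natural"),
    unnatural = check_rr(unnatural, "unnatural"),
    provenance = provenance %||% "stratum-specific relative risks",
    approximation = FALSE
  )
}

validate_config <- function(cfg) {
  cz <- cfg$causes
  sets <- cz[c("mental_core", "substance", "neurological",
               "musculoskeletal_pain", "self_harm")]
  all_members <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    abort(sprintf(
      "Cause sets must be pairwise disjoint; duplicated: %s",
      paste(unique(all_members[duplicated(all_members)]), collapse = ", ")
    ))
  }
  if (!(cfg$msk_fraction >= 0 && cfg$msk_fraction <= 1)) {
    abort("`msk_fraction` must lie in [0, 1].")
  }
  b <- cfg$msk_fraction_bounds
  if (length(b) != 2 || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
    abort("`msk_fraction_bounds` must be ordered and within [0, 1].")
  }
  if (!all(c("original", "reallocation", "composite") %in% names(cfg$include_substance))) {
    abort("`include_substance` must name all three approaches.")
  }
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Reads a YAML file with any subset of the fields of [default_config()]
#' (`causes`, `msk_fraction`, `msk_fraction_bounds`, `rr`, `include_substance`,
#' `composite_self_harm_yld`, `year`); unspecified fields keep their
#' defaults. The `rr` block may contain `natural`/`unnatural` or `all_cause`
#' entries, each with `point`, `lower`, `upper`.
#'
#' @param path path to a YAML file. The packaged default lives at
#'   `system.file("extdata", "default_config.yaml", package = "mhburden")`.
#' @return an `mh_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rr <- if (!is.null(raw$rr)) {
    rr_config(
      natural = raw$rr$natural, unnatural = raw$rr$unnatural,
      all_cause = raw$rr$all_cause, provenance = raw$rr$provenance
    )
  } else {
    rr_config(all_cause = list(point = 2.2, lower = 2.1, upper = 2.3))
  }
  inc <- raw$include_substance
  include_substance <- if (is.null(inc)) {
    c(original = FALSE, reallocation = TRUE, composite = TRUE)
  } else {
    vapply(c("original", "reallocation", "composite"),
           function(a) isTRUE(inc[[a]]), logical(1))
  }
  default_config(
    causes = raw$causes %||% list(),
    msk_fraction = raw$msk_fraction %||% (1 / 3),
    msk_fraction_bounds = unlist(raw$msk_fraction_bounds %||% c(1 / 6, 1 / 2)),
    rr = rr,
    include_substance = include_substance,
    composite_self_harm_yld = isTRUE(raw$composite_self_harm_yld),
    year = raw$year %||% 2019
  )
}

#' Cause levels implied by a configuration
#'
#' Returns the hierarchy level of every cause named in the configuration:
#' level 0 for all causes combined, level 1 for the NCD and injuries roots,
#' level 2 for the aggregate mental-disorders cause, level 3 for the
#' individual causes in the configured sets.
#'
#' @param config an `mh_config` list.
#' @return tibble with columns `cause`, `cause_level`.
#' @export
cause_levels <- function(config = default_config()) {
  cz <- config$causes
  bind_rows(
    tibble(cause = cz$all_cause, cause_level = 0L),
    tibble(cause = c(cz$ncd_root, cz$injuries_root), cause_level = 1L),
    tibble(cause = cz$prevalence_cause, cause_level = 2L),
    tibble(
      cause = c(cz$mental_core, cz$substance, cz$neurological,
                cz$musculoskeletal_pain, cz$self_harm),
      cause_level = 3L
    )
  ) %>% distinct(.data$cause, .keep_all = TRUE)
}

approach_levels <- c("original", "reallocation", "composite")

direct_causes <- function(config, approach) {
  cz <- config$causes
  out <- cz$mental_core
  if (isTRUE(config$include_substance[[approach]])) out <- c(out, cz$substance)
  if (approach %in% c("reallocation", "composite")) out <- c(out, cz$neurological)
  if (approach == "reallocation") out <- c(out, cz$self_harm)
  out
}

#' Allocation rule for a cause under an approach
#'
#' Looks up how a cause's burden is attributed to mental disorders under each
#' of the three estimation approaches: in full (`full`), as a fixed fraction
#' (`fractional`, used for the chronic-pain share of musculoskeletal
#' disorders), through the mortality PAF (`paf_mortality`, the composite
#' approach's treatment of self-harm and of NCD premature mortality), or not
#' at all (`excluded`).
#'
#' @param cause character vector of cause names.
#' @param approach one of `"original"`, `"reallocation"`, `"composite"`.
#' @param config an `mh_config` list.
#' @param strict if `TRUE` (default) an unknown cause is an error; if
#'   `FALSE` it is returned as `excluded` with a warning.
#' @return tibble with columns `cause`, `approach`, `mode`, `fraction`,
#'   `measures` (`"all"` or `"YLL"`).
#' @export
#' @examples
#' allocation_rule("Schizophrenia", "original")
#' allocation_rule("Self-harm", "composite")
allocation_rule <- function(cause, approach = approach_levels,
                            config = default_config(), strict = TRUE) {
  approach <- match.arg(approach)
  cz <- config$causes
  known <- c(
    cz$mental_core, cz$substance, cz$neurological, cz$musculoskeletal_pain,
    cz$self_harm, cz$ncd_root, cz$injuries_root, cz$all_cause,
    cz$prevalence_cause
  )
  unknown <- setdiff(cause, known)
  if (length(unknown) > 0) {
    msg <- sprintf("Unknown cause(s) under the configured taxonomy: %s",
                   paste(unknown, collapse = ", "))
    if (strict) abort(msg) else warn(paste0(msg, "; treating as excluded."))
  }
  rule_one <- function(cs) {
    direct <- cs %in% direct_causes(config, approach)
    msk <- cs %in% cz$musculoskeletal_pain
    sh <- cs %in% cz$self_harm
    if (direct) {
      list(mode = "full", fraction = 1, measures = "all")
    } else if (msk && approach %in% c("reallocation", "composite")) {
      list(mode = "fractional", fraction = config$msk_fraction, measures = "all")
    } else if (sh && approach == "composite") {
      list(mode = "paf_mortality", fraction = 0, measures = "YLL")
    } else if (cs %in% cz$ncd_root && approach == "composite") {
      list(mode = "paf_mortality", fraction = 0, measures = "YLL")
    } else {
      list(mode = "excluded", fraction = 0, measures = "all")
    }
  }
  rules <- purrr::map(cause, rule_one)
  tibble(
    cause = cause,
    approach = approach,
    mode = purrr::map_chr(rules, "mode"),
    fraction = purrr::map_dbl(rules, "fraction"),
    measures = purrr::map_chr(rules, "measures")
  )
}

#' Mortality bases for PAF attribution
#'
#' Computes, per location, the YLL (or death) bases the mortality PAF is
#' applied to under the composite approach: the natural-cause base is the NCD
#' total minus the burden of causes already attributed directly (in full or
#' fractionally), so that no burden is counted twice; the unnatural-cause
#' base is the injuries total (self-harm included). A negative natural base
#' after subtraction signals an inconsistent hierarchy and is clamped to
#' zero with a warning.
#'
#' @param burden canonical burden tibble (counts).
#' @param config an `mh_config` list.
#' @param measure `"YLLs"` or `"Deaths"`.
#' @param value_col which value column to use: `"val"`, `"lower"`, `"upper"`.
#' @param msk_fraction override of the configured fraction (used by the
#'   sensitivity bounds).
#' @return tibble with columns `location`, `natural_base`, `unnatural_base`.
#' @export
paf_mortality_base <- function(burden, config = default_config(),
                               measure = c("YLLs", "Deaths"),
                               value_col = "val", msk_fraction = NULL) {
  measure <- match.arg(measure)
  msk_fraction <- msk_fraction %||% config$msk_fraction
  cz <- config$causes
  m <- burden %>%
    filter(.data$measure == !!measure, .data$metric == "count")
  v <- function(tbl) {
    tbl %>%
      group_by(.data$location) %>%
      summarise(x = sum(.data[[value_col]]), .groups = "drop")
  }
  locs <- tibble(location = sort(unique(m$location)))
  sum_over <- function(causes) {
    locs %>%
      left_join(v(filter(m, .data$cause %in% causes)), by = "location") %>%
      mutate(x = dplyr::coalesce(.data$x, 0)) %>%
      pull(.data$x)
  }
  direct <- sum_over(direct_causes(config, "composite")) +
    msk_fraction * sum_over(cz$musculoskeletal_pain)
  ncd <- sum_over(cz$ncd_root)
  inj <- sum_over(cz$injuries_root)
  natural <- ncd - direct
  if (any(natural < 0)) {
    warn(sprintf(
      "Directly attributed %s exceed the NCD total for %d location(s); clamping the natural base to 0 (inconsistent input hierarchy?).",
      measure, sum(natural < 0)
    ))
    natural <- pmax(natural, 0)
  }
  tibble(location = locs$location, natural_base = natural, unnatural_base = inj)
}
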