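#' Specification of the three-way sensitivity analysis
#'
#' The uncertainty interval around every result is built from three sources,
#' each of which can be switched off: (1) the uncertainty intervals the
#' burden study publishes for every burden quantity, (2) the 95% confidence
#' interval of the pooled mortality relative risk together with the
#' prevalence interval, and (3) the reallocated share of musculoskeletal-pain
#' burden, varied from one sixth (lower) through one third (point) to one
#' half (upper).
#'
#' @param use_gbd_ui use the burden table's lower/upper columns.
#' @param use_rr_ci use the RR confidence interval.
#' @param prevalence_bounds use the prevalence rows' lower/upper columns.
#' @param msk_fraction_bounds length-2 numeric or `NULL` to hold the
#'   fraction at its point value.
#' @return a list with class `mh_sensitivity_spec`.
#' @export
sensitivity_spec <- function(use_gbd_ui = TRUE, use_rr_ci = TRUE,
                             prevalence_bounds = TRUE,
                             msk_fraction_bounds = c(1 / 6, 1 / 2)) {
  if (!is.null(msk_fraction_bounds)) {
    stopifnot(length(msk_fraction_bounds) == 2,
              msk_fraction_bounds[1] <= msk_fraction_bounds[2],
              msk_fraction_bounds[1] >= 0, msk_fraction_bounds[2] <= 1)
  }
  structure(
    list(
      use_gbd_ui = use_gbd_ui, use_rr_ci = use_rr_ci,
      prevalence_bounds = prevalence_bounds,
      msk_fraction_bounds = msk_fraction_bounds
    ),
    class = "mh_sensitivity_spec"
  )
}

#' Attribution with lower/upper sensitivity bounds
#'
#' Runs the attribution engine three times — once at all-lower settings, once
#' at point settings, once at all-upper settings (concordant extremes, the
#' way the source tables present one interval per cell rather than a
#' simulation) — and returns the point results with `lower` and `upper`
#' columns. The lower run combines the lower burden intervals, lower
#' prevalence, the lower end of the RR confidence interval, and the lower
#' musculoskeletal fraction; the upper run the upper analogues.
#'
#' The sandwich `lower <= attributable <= upper` is asserted for every
#' location x measure cell: a genuine violation (beyond floating-point
#' round-off, which is clamped) aborts, since it signals a configuration
#' under which the pipeline is not monotone in its inputs. Note the msk
#' fraction makes individual *components* non-monotone (a smaller fraction
#' shrinks the direct component but enlarges the natural PAF base); totals
#' remain ordered because the PAF is below 1.
#'
#' @inheritParams run_approach
#' @param spec an [sensitivity_spec()] object.
#' @return an `mh_attribution` tibble with additional `lower` and `upper`
#'   columns (and component breakdowns for the point run).
#' @export
#' @examples
#' w <- generate_world(world_config(n_countries = 4, seed = 1))
#' bound_run(w$burden, "composite")
bound_run <- function(burden,
                      approach = c("original", "reallocation", "composite"),
                      config = default_config(),
                      spec = sensitivity_spec(),
                      prevalence_mode = "any_disorder") {
  approach <- match.arg(approach)
  msk_b <- spec$msk_fraction_bounds %||% rep(config$msk_fraction, 2)
  one <- function(value_col, prevalence_col, rr_bound, mskf) {
    run_approach(
      burden, approach, config,
      value_col = value_col,
      msk_fraction = mskf,
      rr_bound = rr_bound,
      prevalence_col = prevalence_col,
      prevalence_mode = prevalence_mode
    )
  }
  point <- one("val", "val", "point", config$msk_fraction)
  lo <- one(
    if (spec$use_gbd_ui) "lower" else "val",
    if (spec$prevalence_bounds) "lower" else "val",
    if (spec$use_rr_ci) "lower" else "point",
    msk_b[1]
  )
  hi <- one(
    if (spec$use_gbd_ui) "upper" else "val",
    if (spec$prevalence_bounds) "upper" else "val",
    if (spec$use_rr_ci) "upper" else "point",
    msk_b[2]
  )
  key <- c("location", "approach", "measure")
  stopifnot(identical(point[key], lo[key]), identical(point[key], hi[key]))
  out <- point
  out$lower <- lo$attributable
  out$upper <- hi$attributable

  # enforce the sandwich; tolerate (and clamp) only float round-off
  slack <- 1e-9 * pmax(abs(out$attributable), 1)
  bad <- out$lower > out$attributable + slack | out$upper < out$attributable - slack
  if (any(bad)) {
    abort(sprintf(
      "Bound ordering violated for %d cell(s) (e.g. %s / %s): the configuration is not monotone in its inputs.",
      sum(bad), out$location[bad][1], out$measure[bad][1]
    ))
  }
  out$lower <- pmin(out$lower, out$attributable)
  out$upper <- pmax(out$upper, out$attributable)
  class(out) <- c("mh_attribution", setdiff(class(out), "mh_attribution"))
  out
}
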