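# Fixture builders: every fixture is constructed in code.

burden_rows <- function(location, cause, measure, val,
                        lower = val, upper = val, metric = "count",
                        cause_level = 3L, year = 2019L) {
  tibble::tibble(
    measure = measure, location = location, cause = cause,
    cause_level = as.integer(cause_level), metric = metric,
    year = as.integer(year), val = val, lower = lower, upper = upper
  )
}

# One-country fixture engineered for hand-checked composite arithmetic:
# prevalence 0.15, an NCD YLL base of 1180 with nothing directly attributed,
# an injuries YLL base of 590.
micro_composite_burden <- function(prevalence = 0.15) {
  dplyr::bind_rows(
    burden_rows("A", "Non-communicable diseases", "YLLs", 1180, cause_level = 1L),
    burden_rows("A", "Injuries", "YLLs", 590, cause_level = 1L),
    burden_rows("A", "Schizophrenia", "YLDs", 0),
    burden_rows("A", "Mental disorders", "Prevalence", prevalence,
                metric = "proportion", cause_level = 2L)
  )
}

# One-country fixture whose only burden is musculoskeletal-pain DALYs.
msk_only_burden <- function(dalys = 300) {
  burden_rows("A", "Low back pain", "DALYs", dalys)
}

# Write a name-dialect GHDx CSV for a canonical burden tibble.
write_ghdx_fixture <- function(burden, path, age_name = "All ages",
                               sex_name = "Both") {
  full_measure <- c(
    DALYs = "DALYs (Disability-Adjusted Life Years)",
    YLLs = "YLLs (Years of Life Lost)",
    YLDs = "YLDs (Years Lived with Disability)",
    Deaths = "Deaths", Prevalence = "Prevalence"
  )
  metric_out <- c(count = "Number", rate = "Rate", proportion = "Percent")
  readr::write_csv(tibble::tibble(
    measure_name = unname(full_measure[burden$measure]),
    location_name = burden$location,
    sex_name = sex_name, age_name = age_name,
    cause_name = burden$cause,
    metric_name = unname(metric_out[burden$metric]),
    year = burden$year, val = burden$val,
    upper = burden$upper, lower = burden$lower
  ), path, progress = FALSE)
  path
}

# A small random non-negative burden table over the full taxonomy, for
# property-style checks independent of the world generator's structure.
random_taxonomy_burden <- function(n_countries = 3, seed = 1) {
  cfg <- default_config()
  cz <- cfg$causes
  leaves <- c(cz$mental_core, cz$substance, cz$neurological,
              cz$musculoskeletal_pain, cz$self_harm)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_countries)) {
      loc <- paste0("C", i)
      for (ms in c("YLDs", "YLLs", "Deaths")) {
        v <- stats::runif(length(leaves), 0, 100)
        rows[[length(rows) + 1]] <- burden_rows(loc, leaves, ms, v,
                                                lower = 0.9 * v, upper = 1.1 * v)
        ncd <- sum(v[seq_along(leaves) != length(leaves)]) + stats::runif(1, 50, 500)
        inj <- v[length(leaves)] + stats::runif(1, 10, 200)
        rows[[length(rows) + 1]] <- burden_rows(
          loc, c(cz$ncd_root, cz$injuries_root), ms, c(ncd, inj),
          lower = 0.9 * c(ncd, inj), upper = 1.1 * c(ncd, inj), cause_level = 1L
        )
      }
      p <- stats::runif(1, 0.05, 0.2)
      rows[[length(rows) + 1]] <- burden_rows(
        loc, "Mental disorders", "Prevalence", p, lower = 0.9 * p,
        upper = min(1, 1.1 * p), metric = "proportion", cause_level = 2L
      )
    }
    dplyr::bind_rows(rows)
  })
}
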