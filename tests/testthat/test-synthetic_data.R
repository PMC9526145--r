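test_that("generation is deterministic and leaves the RNG state alone", {
  w1 <- generate_world(world_config(n_countries = 6, seed = 101))
  w2 <- generate_world(world_config(n_countries = 6, seed = 101))
  expect_identical(w1$burden, w2$burden)
  expect_identical(w1$econ, w2$econ)
  expect_identical(w1$ground_truth, w2$ground_truth)
  w3 <- generate_world(world_config(n_countries = 6, seed = 102))
  expect_false(identical(w1$burden$val, w3$burden$val))
})

test_that("written worlds are byte-identical across runs", {
  w <- generate_world(world_config(n_countries = 4, seed = 103))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_world(w, d1); p2 <- write_world(w, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})

test_that("invalid configurations fail before generation", {
  expect_error(world_config(n_countries = 0), "n_countries")
  expect_error(world_config(cause_mix = c(mental = 1)), "cause_mix")
  bad_mix <- c(mental = 0.5, substance = 0.02, neurological = 0.05,
               musculoskeletal = 0.06, self_harm = 0.02, other_ncd = 0.52,
               other_injuries = 0.08, cmnn = 0.20)
  expect_error(world_config(cause_mix = bad_mix), "sum to 1")
  expect_error(world_config(ui_halfwidth = 1.2), "ui_halfwidth")
  expect_error(world_config(prevalence_range = c(0.5, 0.1)), "ordered")
})

test_that("a single-country noiseless world is recovered exactly", {
  w <- generate_world(world_config(n_countries = 1, n_regions = 1,
                                   n_unclassified = 0, seed = 104,
                                   ui_halfwidth = 0, prevalence_halfwidth = 0))
  res <- run_all_approaches(w$burden)
  gt <- w$ground_truth
  for (a in c("original", "reallocation", "composite")) {
    for (ms in c("dalys", "ylds", "ylls", "deaths")) {
      col <- paste0(a, "_", ms)
      msr <- c(dalys = "DALYs", ylds = "YLDs", ylls = "YLLs", deaths = "Deaths")[ms]
      got <- res$attributable[res$approach == a & res$measure == msr]
      expect_equal(got, gt[[col]], tolerance = 1e-12)
    }
  }
})

test_that("generated files round-trip through the readers with no rejected rows", {
  w <- generate_world(world_config(n_countries = 5, seed = 105))
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  b <- read_burden_table(paths[["burden"]])
  expect_equal(attr(b, "rows_rejected"), 0L)
  expect_equal(nrow(b), nrow(w$burden))
  expect_equal(
    dplyr::arrange(b[, c("measure", "location", "cause", "val")],
                   measure, location, cause),
    dplyr::arrange(w$burden[, c("measure", "location", "cause", "val")],
                   measure, location, cause),
    ignore_attr = TRUE
  )
  pop <- readr::read_csv(paths[["population"]], show_col_types = FALSE)
  econ <- read_econ_table(paths[["econ"]], pop)
  expect_equal(sort(econ$gdp_pc), sort(w$econ$gdp_pc), tolerance = 1e-9)
  set <- harmonize_locations(b, econ,
                             readr::read_csv(paths[["locations"]],
                                             show_col_types = FALSE))
  expect_equal(length(attr(set, "unmatched_econ")), 0)
})

test_that("per-disorder prevalences compose back to the any-disorder aggregate", {
  w <- generate_world(world_config(n_countries = 5, seed = 106))
  any <- country_prevalence(w$burden, "any_disorder")
  prod <- country_prevalence(w$burden, "complement_product")
  expect_equal(prod$prevalence, any$prevalence, tolerance = 1e-9)
})

test_that("the planted income gradient is recovered", {
  flat <- generate_world(world_config(n_countries = 40, seed = 107,
                                      income_gradient = 1))
  expect_equal(income_gradient_check(flat), 1, tolerance = 0.1)
  steep <- generate_world(world_config(n_countries = 40, seed = 107,
                                       income_gradient = 2))
  expect_equal(income_gradient_check(steep), 2, tolerance = 0.1)
  single <- generate_world(world_config(n_countries = 6, seed = 108,
                                        income_tiers = "Low income",
                                        n_unclassified = 0))
  expect_error(income_gradient_check(single), "fewer than 2")
})

test_that("world summaries expose the planted parameters", {
  w <- generate_world(world_config(n_countries = 5, seed = 109))
  g <- glance(w)
  expect_equal(g$n_countries, 5)
  expect_equal(g$rr_natural, 2.2)
  expect_identical(tidy(w), w$burden)
})
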