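test_that("allocation rules reproduce the three-approach table", {
  expect_equal(
    allocation_rule("Schizophrenia", "original")[, c("mode", "fraction")],
    tibble::tibble(mode = "full", fraction = 1)
  )
  # self-harm: full under reallocation, PAF-based mortality under composite
  expect_equal(allocation_rule("Self-harm", "reallocation")$mode, "full")
  sh <- allocation_rule("Self-harm", "composite")
  expect_equal(sh$mode, "paf_mortality")
  expect_equal(sh$measures, "YLL")
  # chronic-pain musculoskeletal causes: one third under both expanded approaches
  msk <- allocation_rule("Low back pain", "composite")
  expect_equal(msk$mode, "fractional")
  expect_equal(msk$fraction, 1 / 3)
  # neurological: excluded originally, full under the expanded approaches
  expect_equal(allocation_rule("Headache disorders", "original")$mode, "excluded")
  expect_equal(allocation_rule("Headache disorders", "reallocation")$mode, "full")
  # substance use: excluded from the original preset, included elsewhere
  expect_equal(allocation_rule("Alcohol use disorders", "original")$mode, "excluded")
  expect_equal(allocation_rule("Alcohol use disorders", "composite")$mode, "full")
})

test_that("unknown causes error under strict mode, fall to excluded when lenient", {
  expect_error(allocation_rule("Maternal disorders", "composite"), "Unknown cause")
  expect_warning(
    r <- allocation_rule("Maternal disorders", "composite", strict = FALSE),
    "excluded"
  )
  expect_equal(r$mode, "excluded")
  expect_equal(r$fraction, 0)
})

test_that("config validation rejects overlapping sets and bad fractions", {
  expect_error(
    default_config(causes = list(substance = "Schizophrenia")),
    "disjoint"
  )
  expect_error(default_config(msk_fraction = 1.2), "msk_fraction")
  expect_error(default_config(msk_fraction_bounds = c(0.5, 0.2)), "ordered")
})

test_that("relative risks require explicit configuration", {
  expect_error(rr_config(), "required")
  expect_error(rr_config(natural = list(point = 2, lower = 1.9, upper = 2.1)),
               "both")
  ac <- rr_config(all_cause = list(point = 2.2, lower = 2.1, upper = 2.3))
  expect_true(ac$approximation)
  expect_equal(ac$natural$point, 2.2)
  expect_equal(ac$unnatural, ac$natural)
  expect_error(
    rr_config(all_cause = list(point = 2.2, lower = 2.3, upper = 2.1)),
    "lower <= point <= upper"
  )
})

test_that("the YAML default config round-trips against the in-code default", {
  path <- system.file("extdata", "default_config.yaml", package = "mhburden")
  cfg <- read_config(path)
  def <- default_config()
  expect_equal(cfg$causes, def$causes)
  expect_equal(cfg$msk_fraction, def$msk_fraction, tolerance = 1e-12)
  expect_equal(cfg$rr$natural$point, def$rr$natural$point)
  expect_equal(cfg$include_substance, def$include_substance)
})

test_that("mortality bases subtract directly attributed burden from the NCD total", {
  b <- dplyr::bind_rows(
    burden_rows("A", "Non-communicable diseases", "YLLs", 1000, cause_level = 1L),
    burden_rows("A", "Injuries", "YLLs", 500, cause_level = 1L),
    burden_rows("A", "Schizophrenia", "YLLs", 120),
    burden_rows("A", "Alcohol use disorders", "YLLs", 30),
    burden_rows("A", "Headache disorders", "YLLs", 20),
    burden_rows("A", "Low back pain", "YLLs", 90) # 1/3 of 90 = 30
  )
  base <- paf_mortality_base(b, measure = "YLLs")
  expect_equal(base$natural_base, 1000 - (120 + 30 + 20 + 30))
  expect_equal(base$unnatural_base, 500)
})

test_that("a negative natural base is clamped to zero with a warning", {
  b <- dplyr::bind_rows(
    burden_rows("A", "Non-communicable diseases", "YLLs", 100, cause_level = 1L),
    burden_rows("A", "Injuries", "YLLs", 50, cause_level = 1L),
    burden_rows("A", "Schizophrenia", "YLLs", 150)
  )
  expect_warning(base <- paf_mortality_base(b, measure = "YLLs"), "clamping")
  expect_equal(base$natural_base, 0)
  expect_equal(base$unnatural_base, 50)
})

test_that("cause levels cover the configured taxonomy", {
  lv <- cause_levels()
  expect_equal(lv$cause_level[lv$cause == "All causes"], 0L)
  expect_equal(lv$cause_level[lv$cause == "Mental disorders"], 2L)
  expect_equal(lv$cause_level[lv$cause == "Schizophrenia"], 3L)
  expect_false(anyDuplicated(lv$cause) > 0)
})
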