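test_that("the original approach sums the core mental causes in full", {
  b <- burden_rows("A", "Schizophrenia", "DALYs", 10)
  got <- run_approach(b, "original")
  expect_equal(got$attributable[got$measure == "DALYs"], 10)

  none <- burden_rows("A", "Other injuries", "DALYs", 50)
  expect_equal(run_approach(none, "original")$attributable, 0)

  # brute-force per-country sums on a 3-country fixture
  withr::local_seed(4)
  cz <- default_config()$causes
  vals <- matrix(stats::runif(30, 0, 10), nrow = 3)
  b3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    burden_rows(paste0("C", i), cz$mental_core, "DALYs", vals[i, ])
  }))
  got <- run_approach(b3, "original")
  expect_equal(got$attributable, rowSums(vals))
})

test_that("the reallocation approach applies the musculoskeletal fraction", {
  b <- msk_only_burden(300)
  expect_equal(run_approach(b, "reallocation")$attributable, 100,
               tolerance = 1e-12)
  expect_equal(run_approach(b, "reallocation", msk_fraction = 1 / 6)$attributable,
               50, tolerance = 1e-12)
  expect_equal(run_approach(b, "reallocation", msk_fraction = 1 / 2)$attributable,
               150, tolerance = 1e-12)
  zero <- dplyr::mutate(b, val = 0, lower = 0, upper = 0)
  expect_equal(run_approach(zero, "reallocation")$attributable, 0)
})

test_that("composite with zero prevalence equals reallocation minus self-harm", {
  b <- random_taxonomy_burden(n_countries = 3, seed = 8)
  b$val[b$measure == "Prevalence"] <- 0
  b$lower[b$measure == "Prevalence"] <- 0
  b$upper[b$measure == "Prevalence"] <- 0
  comp <- run_approach(b, "composite")
  real <- run_approach(b, "reallocation")
  sh <- b[b$cause == "Self-harm" & b$metric == "count", ]
  for (ms in c("YLDs", "YLLs", "Deaths", "DALYs")) {
    sh_ms <- if (ms == "DALYs") {
      sum(sh$val[sh$measure %in% c("YLDs", "YLLs")])
    } else {
      sum(sh$val[sh$measure == ms])
    }
    by_loc <- merge(comp[comp$measure == ms, ], real[real$measure == ms, ],
                    by = "location")
    expect_equal(sum(by_loc$attributable.x), sum(by_loc$attributable.y) - sh_ms,
                 tolerance = 1e-9)
  }
})

test_that("the hand-checked composite micro-example reproduces", {
  got <- run_approach(micro_composite_burden(), "composite")
  yll <- got[got$measure == "YLLs", ]
  paf <- 0.15 * 1.2 / (1 + 0.15 * 1.2)
  expect_equal(yll$component_paf_natural, paf * 1180, tolerance = 1e-12)
  expect_equal(yll$component_paf_unnatural, paf * 590, tolerance = 1e-12)
  expect_equal(yll$attributable, 270, tolerance = 1e-9)
})

test_that("DALY additivity and component conservation hold on generated worlds", {
  w <- generate_world(world_config(n_countries = 12, seed = 21))
  res <- run_all_approaches(w$burden)
  wide <- tidyr::pivot_wider(
    res[, c("location", "approach", "measure", "attributable")],
    names_from = "measure", values_from = "attributable"
  )
  expect_identical(wide$DALYs, wide$YLLs + wide$YLDs)
  comp_sum <- ((res$component_direct + res$component_msk) +
                 res$component_paf_natural) + res$component_paf_unnatural
  expect_equal(res$attributable, comp_sum, tolerance = 1e-12)
})

test_that("original never exceeds reallocation on arbitrary non-negative inputs", {
  for (seed in c(1, 2, 3)) {
    b <- random_taxonomy_burden(n_countries = 4, seed = seed)
    o <- run_approach(b, "original")
    r <- run_approach(b, "reallocation")
    expect_true(all(o$attributable <= r$attributable + 1e-12))
  }
})

test_that("composite attribution is monotone in prevalence and RR", {
  b <- random_taxonomy_burden(n_countries = 3, seed = 13)
  base <- run_approach(b, "composite")
  up_p <- b
  idx <- up_p$measure == "Prevalence"
  up_p$val[idx] <- pmin(1, up_p$val[idx] * 1.5)
  up_p$upper[idx] <- pmax(up_p$upper[idx], up_p$val[idx])
  expect_true(all(run_approach(up_p, "composite")$attributable >=
                    base$attributable - 1e-12))

  cfg_hi <- default_config(
    rr = rr_config(all_cause = list(point = 3.0, lower = 2.8, upper = 3.2))
  )
  expect_true(all(run_approach(b, "composite", cfg_hi)$attributable >=
                    base$attributable - 1e-12))
})

test_that("protective relative risks are refused", {
  b <- random_taxonomy_burden(n_countries = 2, seed = 3)
  cfg <- default_config(
    rr = rr_config(all_cause = list(point = 0.8, lower = 0.7, upper = 0.9))
  )
  expect_error(run_approach(b, "composite", cfg), "[Pp]rotective")
})

test_that("the composite approach demands prevalence for every country", {
  b <- random_taxonomy_burden(n_countries = 2, seed = 5)
  b <- b[!(b$measure == "Prevalence" & b$location == "C2"), ]
  expect_error(run_approach(b, "composite"), "C2")
})
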