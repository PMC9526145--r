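test_that("a well-formed name-dialect file reads back value-identical", {
  b <- dplyr::bind_rows(
    burden_rows("Aland", "Schizophrenia", "DALYs", 12.5, 10, 15),
    burden_rows("Borland", "Self-harm", "YLLs", 7.25, 6, 9)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_ghdx_fixture(b, path)
  got <- read_burden_table(path)
  expect_equal(nrow(got), 2)
  expect_equal(got$val, b$val)
  expect_equal(got$lower, b$lower)
  expect_equal(got$measure, b$measure)
  expect_equal(attr(got, "rows_in"), 2L)
})

test_that("interval violations and unknown labels are rejected with context", {
  b <- burden_rows("A", "Schizophrenia", "DALYs", 5, lower = 10, upper = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ghdx_fixture(b, path)
  expect_error(read_burden_table(path), "lower <= val <= upper.*1")

  raw <- readr::read_csv(write_ghdx_fixture(
    burden_rows("A", "X", "DALYs", 5), path
  ), show_col_types = FALSE)
  raw$measure_name <- "Hospitalizations"
  readr::write_csv(raw, path)
  expect_error(read_burden_table(path), "Unknown measure")

  raw$measure_name <- "Deaths"
  raw$metric_name <- "Furlongs"
  readr::write_csv(raw, path)
  expect_error(read_burden_table(path), "Unknown metric")
})

test_that("missing required columns are named in the error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(measure_name = "Deaths", val = 1), path)
  expect_error(read_burden_table(path), "location_name")
})

test_that("rate rows convert to counts via population, and back", {
  b <- burden_rows("A", "Schizophrenia", "DALYs", 50, 40, 60, metric = "rate")
  pop <- tibble::tibble(location = "A", population = 2e6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ghdx_fixture(b, path)
  got <- read_burden_table(path, population = pop)
  # 50 per 100k of 2 million people
  expect_equal(got$val, 50 * 2e6 / 1e5)
  expect_equal(got$metric, "count")

  back <- convert_burden_metric(got, "rate", pop)
  expect_equal(back$val, 50, tolerance = 1e-9)
  expect_equal(back$lower, 40, tolerance = 1e-9)
})

test_that("stratified rows are rejected but accounted for", {
  b <- burden_rows(c("A", "A"), "Schizophrenia", "DALYs", c(5, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ghdx_fixture(b, path, age_name = c("All ages", "15-49 years"))
  expect_message(got <- read_burden_table(path), "Rejecting 1 row")
  expect_equal(nrow(got), 1)
  expect_equal(
    attr(got, "rows_in"),
    attr(got, "rows_kept") + attr(got, "rows_rejected")
  )
})

test_that("id and name dialects of the same world read identically", {
  w <- generate_world(world_config(n_countries = 4, seed = 11))
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir, dialects = c("name", "id"))
  by_name <- read_burden_table(paths[["burden"]])
  lk <- list(
    locations = readr::read_csv(paths[["lookup_locations"]], show_col_types = FALSE),
    causes = readr::read_csv(paths[["lookup_causes"]], show_col_types = FALSE)
  )
  by_id <- read_burden_table(paths[["burden_id"]], lookup = lk)
  cols <- c("measure", "location", "cause", "metric", "val", "lower", "upper")
  expect_equal(
    dplyr::arrange(by_name[cols], measure, location, cause),
    dplyr::arrange(by_id[cols], measure, location, cause),
    ignore_attr = TRUE
  )
})

test_that("canonical write/read round-trip is value-identical", {
  w <- generate_world(world_config(n_countries = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_burden_table(w$burden, path)
  got <- read_canonical_burden(path)
  expect_equal(got$val, w$burden$val)
  expect_equal(got$lower, w$burden$lower)
  expect_equal(got$cause, w$burden$cause)
})

test_that("per-capita GDP uses the supplied population, with exclusions warned", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    location = c("A", "B", "C"), year = 2019,
    gdp_usd = c(2.0e10, 5e9, 1e9)
  ), path)
  pop <- tibble::tibble(location = c("A", "B"), population = c(2.0e6, 1e6))
  expect_warning(econ <- read_econ_table(path, pop), "absent from the population")
  expect_equal(econ$gdp_pc[econ$location == "A"], 10000)
  expect_false("C" %in% econ$location)
  expect_true("C" %in% attr(econ, "excluded"))
})

test_that("per-capita values match row-by-row recomputation on a 5-country table", {
  withr::local_seed(2)
  gdp <- stats::runif(5, 1e9, 1e12)
  popv <- stats::runif(5, 1e5, 1e8)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    location = paste0("L", 1:5), year = 2019, gdp_usd = gdp
  ), path)
  econ <- read_econ_table(path, tibble::tibble(location = paste0("L", 1:5),
                                               population = popv))
  for (i in 1:5) {
    expect_identical(econ$gdp_pc[econ$location == paste0("L", i)], gdp[i] / popv[i])
  }
})

test_that("zero or missing population for a matched location is an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(location = "A", year = 2019, gdp_usd = 1e9), path)
  expect_error(
    read_econ_table(path, tibble::tibble(location = "A", population = 0)),
    "Zero or missing population"
  )
})

test_that("the WDI wide dialect is parsed and the year selected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    `Country Name` = c("A", "A"), `Country Code` = "XAA",
    `Indicator Name` = c("GDP (current US$)", "GDP, PPP (current international $)"),
    `Indicator Code` = c("NY.GDP.MKTP.CD", "NY.GDP.MKTP.PP.CD"),
    `2018` = c(9e9, 1.8e10), `2019` = c(1e10, 2e10)
  ), path)
  econ <- read_econ_table(path, tibble::tibble(location = "A", population = 1e6),
                          year = 2019)
  expect_equal(econ$gdp_usd, 1e10)
  expect_equal(econ$gdp_ppp_pc, 2e4)
})

test_that("location harmonization joins labels, drops aggregates, resolves aliases", {
  map <- tibble::tibble(
    location = c("Viet Nam", "Alphaland", "Betaland"),
    iso3 = c("VNM", "XAL", "XBE"),
    gbd_region = c("Southeast Asia", "Region X", "Region X"),
    income_group = c("Lower-middle income", "High income", "Unclassified")
  )
  burden <- burden_rows(c("Vietnam", "Alphaland", "Betaland"),
                        "Schizophrenia", "DALYs", c(1, 2, 3))
  econ <- tibble::tibble(location = c("Vietnam", "Alphaland", "Betaland", "World"),
                         iso3 = NA, year = 2019, gdp_usd = 1:4 * 1e9,
                         gdp_ppp = NA, population = 1e6,
                         gdp_pc = 1:4 * 1e3, gdp_ppp_pc = NA)
  expect_warning(set <- harmonize_locations(burden, econ, map), "World")
  expect_s3_class(set, "mh_analysis_set")
  expect_equal(nrow(set$burden), 3)
  expect_equal(sort(unique(set$burden$iso3)), c("VNM", "XAL", "XBE"))
  # the name variant was folded onto the canonical map name
  expect_true("Viet Nam" %in% set$burden$location)
  expect_equal(attr(set, "unmatched_econ"), "World")

  expect_error(
    harmonize_locations(burden_rows("Nowhere", "Schizophrenia", "DALYs", 1),
                        econ, map),
    "Nowhere"
  )
})
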