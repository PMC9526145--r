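Package: mhburden
Title: Composite Estimation of the Global Burden and Economic Value of Mental Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for estimating the burden of mental
    disorders beyond the conventional cause hierarchy of global burden of
    disease studies. Implements three allocation approaches (the original
    hierarchical allocation, a morbidity reallocation across neurological,
    substance-use, chronic-pain and self-harm causes, and a composite approach
    that adds premature mortality attributed through population attributable
    fractions computed with Levin's formula), monetary valuation of
    attributable disability-adjusted life years under value-of-a-statistical-
    life style schemes, a three-way sensitivity analysis producing concordant
    lower/upper bounds, aggregation to regions and income groups, and a
    synthetic-data generator that emits realistic burden, economic and
    location tables with embedded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
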