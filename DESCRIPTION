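Package: ewasharvest
Title: Hypothesis-Generating EWAS with Catalog Trait Harvesting and a
    Cohort Hypothesis-Testing Harness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for hypothesis generation from DNA methylation data:
    a minimally adjusted epigenome-wide association scan (EWAS) of a binary
    condition (age and surrogate variables as the only covariates, so that
    confounded signal is deliberately retained), probe-level quality control
    with Tukey-fence outlier masking, surrogate variable analysis with a
    protected exposure, trait harvesting for hit CpGs and their resident
    genes from an EWAS-catalog store, and a logistic-regression harness that
    tests harvested phenotypes against the condition in cohort data.
    Includes a synthetic-data generator that plants the batch and
    common-cause confounding structure the method leverages, plus fixtures
    encoding published summary tables for exact-reproduction tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    sva,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
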