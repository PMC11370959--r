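test_that("identical seeds give byte-identical datasets", {
  a <- generate_dataset(sim_config(n_samples = 50, n_probes = 80, seed = 7))
  b <- generate_dataset(sim_config(n_samples = 50, n_probes = 80, seed = 7))
  expect_identical(a, b)
  c2 <- generate_dataset(sim_config(n_samples = 50, n_probes = 80, seed = 8))
  expect_false(identical(a$beta, c2$beta))
})

test_that("beta values stay in [0,1] even under extreme settings", {
  d <- generate_dataset(sim_config(
    n_samples = 40, n_probes = 60, direct_effect = 0.9,
    confounder_effect_meth = 0.8, batch_effect = 0.9, noise_sd = 0.5,
    seed = 3
  ))
  expect_true(all(d$beta >= 0 & d$beta <= 1))
})

test_that("every probe has exactly one role and counts match config", {
  cfg <- sim_config(n_samples = 30, n_probes = 100, n_direct_probes = 4,
                    n_confounded_probes = 6, n_batch_probes = 10, seed = 1)
  d <- generate_dataset(cfg)
  expect_length(d$truth$roles, 100)
  expect_equal(unname(table(d$truth$roles)[c("direct", "confounded", "batch")]),
               c(4L, 6L, 10L), ignore_attr = TRUE)
})

test_that("inconsistent planted counts are a configuration error", {
  expect_error(
    sim_config(n_probes = 10, n_direct_probes = 5, n_confounded_probes = 5,
               n_batch_probes = 5),
    "inconsistent"
  )
  expect_error(sim_config(baseline_prevalence = 0), "prevalence")
})

test_that("null configuration plants no role-attributable shift", {
  d <- generate_dataset(sim_config(
    n_samples = 200, n_probes = 100, direct_effect = 0,
    confounder_effect_meth = 0, batch_effect = 0, noise_sd = 0.01, seed = 5
  ))
  cases <- d$pheno$sample_id[d$pheno$condition == 1]
  ctrls <- d$pheno$sample_id[d$pheno$condition == 0]
  diffs <- rowMeans(d$beta[, cases, drop = FALSE]) -
    rowMeans(d$beta[, ctrls, drop = FALSE])
  # pure noise: group mean differences of order noise_sd/sqrt(n)
  expect_lt(max(abs(diffs)), 0.01)
})

test_that("confounded probes differ between eventual cases and controls", {
  # Monte-Carlo sign check: the common-cause structure must shift confounded
  # probes upward in cases (positive meth effect x positive log-odds).
  signs <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(
      n_samples = 2000, n_probes = 50, n_direct_probes = 0,
      n_confounded_probes = 10, n_batch_probes = 0,
      confounder_effect_meth = 0.05, confounder_effect_logodds = 1.0,
      noise_sd = 0.02, seed = s
    ))
    conf <- names(d$truth$roles)[d$truth$roles == "confounded"]
    cases <- d$pheno$sample_id[d$pheno$condition == 1]
    ctrls <- d$pheno$sample_id[d$pheno$condition == 0]
    mean(d$beta[conf, cases]) - mean(d$beta[conf, ctrls])
  }, numeric(1))
  expect_true(all(signs > 0))
})

test_that("questionnaire responses are consistent with planted status", {
  d <- generate_dataset(sim_config(n_samples = 300, seed = 11,
                                   n_probes = 20, n_direct_probes = 0,
                                   n_confounded_probes = 0, n_batch_probes = 0))
  st <- derive_status(d$responses)
  joined <- dplyr::left_join(st, d$pheno, by = "sample_id")
  expect_true(all(joined$status[joined$condition == 1] == "case"))
  expect_true(all(joined$status[joined$condition == 0] %in%
                    c("control", "less_severe")))
})

test_that("catalog fixture maps confounded probes to the planted trait", {
  d <- generate_dataset(sim_config(n_samples = 30, n_probes = 40,
                                   n_confounded_probes = 3, n_direct_probes = 2,
                                   n_batch_probes = 5, seed = 2))
  store <- generate_catalog_fixture(d$truth, d$annotation)
  conf <- names(d$truth$roles)[d$truth$roles == "confounded"]
  nulls <- names(d$truth$roles)[d$truth$roles == "null"]
  expect_equal(unique(query_cpg(store, conf[1])$trait), "smoking")
  expect_equal(nrow(query_cpg(store, nulls[1])), 0)
  expect_equal(unique(query_gene(store, "GENE1")$trait), "smoking")
  # zero confounded probes -> empty store
  d0 <- generate_dataset(sim_config(n_samples = 30, n_probes = 40,
                                    n_confounded_probes = 0, n_direct_probes = 2,
                                    n_batch_probes = 5, seed = 2))
  s0 <- generate_catalog_fixture(d0$truth, d0$annotation)
  expect_equal(nrow(s0$records), 0)
  expect_error(
    generate_catalog_fixture(d$truth, d$annotation[-1, ]),
    "absent"
  )
})

test_that("harvest recovers the planted confounder trait across seeds", {
  hitrate <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(n_samples = 500, n_probes = 300,
                                     n_confounded_probes = 5,
                                     n_batch_probes = 20, seed = s))
    store <- generate_catalog_fixture(d$truth, d$annotation)
    ew <- run_ewas(d$beta, d$pheno)
    hits <- select_hits(ew)
    if (!length(hits)) return(FALSE)
    hs <- harvest_traits(hits, d$annotation, store)
    "smoking" %in% hs$trait_norm
  }, logical(1))
  expect_gte(sum(hitrate), 6)
})

test_that("datasets round-trip through plain-text files", {
  d <- generate_dataset(sim_config(n_samples = 25, n_probes = 30, seed = 4,
                                   n_batch_probes = 5, missing_rate = 0.05))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  beta2 <- read_beta_matrix(file.path(dir, "beta.tsv"))
  expect_equal(beta2, d$beta)
  ann2 <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann2$probe_id, d$annotation$probe_id)
  expect_equal(ann2$gene, d$annotation$gene)
})
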