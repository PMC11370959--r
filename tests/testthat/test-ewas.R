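random_design <- function(n, k) {
  x <- cbind(intercept = 1, case = rbinom(n, 1, 0.5))
  if (k > 2) {
    extra <- matrix(rnorm(n * (k - 2)), n, k - 2)
    colnames(extra) <- paste0("z", seq_len(k - 2))
    x <- cbind(x, extra)
  }
  # ensure both classes present
  if (length(unique(x[, "case"])) < 2) x[1:2, "case"] <- c(0, 1)
  x
}

test_that("per-probe OLS matches the normal-equations oracle to 1e-10", {
  withr::with_seed(100, {
    for (i in 1:200) {
      n <- sample(8:30, 1)
      k <- sample(2:5, 1)
      x <- random_design(n, k)
      y <- runif(n)
      if (i %% 5 == 0) y[sample(n, 2)] <- NA  # exercise complete-case path
      got <- fit_probe(y, x)
      if (got$skipped) next
      want <- ols_oracle(y, x, coef_idx = 2)
      expect_equal(got$beta, want$beta, tolerance = 1e-10)
      expect_equal(got$se, want$se, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
      expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
      expect_equal(got$ci_high, want$ci_high, tolerance = 1e-10)
    }
  })
})

test_that("degenerate probes are flagged with no p-value", {
  x <- random_design(12, 2)
  constant <- fit_probe(rep(0.4, 12), x)
  expect_true(constant$degenerate)
  expect_equal(constant$beta, 0)
  expect_true(is.na(constant$p))
  # outcome exactly equal to the case indicator: beta 1, zero residuals
  exact <- fit_probe(x[, "case"], x)
  expect_true(exact$degenerate)
  expect_equal(exact$beta, 1)
  # too few complete cases
  y <- c(0.1, 0.2, rep(NA, 10))
  expect_true(fit_probe(y, x)$skipped)
})

test_that("the vectorised scan path equals the per-probe path", {
  withr::with_seed(7, {
    beta <- make_beta(runif(600), 30, 20)
    pheno <- tibble::tibble(
      sample_id = colnames(beta),
      condition = rep(c(0L, 1L), 10),
      age = sample(c(15L, 17L), 20, replace = TRUE)
    )
    res <- tidy(run_ewas(beta, pheno))
    design <- build_design(pheno)
    for (pid in sample(rownames(beta), 5)) {
      single <- fit_probe(beta[pid, ], design)
      row <- res[res$probe_id == pid, ]
      expect_equal(row$beta, single$beta, tolerance = 1e-12)
      expect_equal(row$p, single$p, tolerance = 1e-12)
    }
  })
})

test_that("null scans are calibrated", {
  d <- generate_dataset(sim_config(
    n_samples = 200, n_probes = 3000, n_direct_probes = 0,
    n_confounded_probes = 0, n_batch_probes = 0, noise_sd = 0.02, seed = 42
  ))
  res <- run_ewas(d$beta, d$pheno)
  frac <- mean(tidy(res)$p < 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / 3000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
  expect_gt(res$lambda, 0.9)
  expect_lt(res$lambda, 1.1)
})

test_that("a planted direct probe ranks at the top of the scan", {
  top10 <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(
      n_samples = 500, n_probes = 1000, n_direct_probes = 1,
      n_confounded_probes = 0, n_batch_probes = 0,
      direct_effect = 0.05, noise_sd = 0.02, seed = s
    ))
    direct <- names(d$truth$roles)[d$truth$roles == "direct"]
    res <- tidy(run_ewas(d$beta, d$pheno))
    direct %in% res$probe_id[1:10]
  }, logical(1))
  expect_gte(sum(top10), 9)
})

test_that("confounded probes surface as hits (leveraging confounding)", {
  found <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(
      n_samples = 500, n_probes = 1000, n_direct_probes = 0,
      n_confounded_probes = 5, n_batch_probes = 0,
      confounder_effect_meth = 0.05, confounder_effect_logodds = 1.0,
      noise_sd = 0.02, seed = s
    ))
    conf <- names(d$truth$roles)[d$truth$roles == "confounded"]
    any(conf %in% select_hits(run_ewas(d$beta, d$pheno)))
  }, logical(1))
  expect_gte(sum(found), 8)
})

test_that("a scan with zero SVs equals the bare intercept+case+age design", {
  withr::with_seed(3, {
    beta <- make_beta(runif(400), 20, 20)
    pheno <- tibble::tibble(
      sample_id = colnames(beta),
      condition = rep(c(0L, 1L), 10),
      age = sample(c(15L, 17L), 20, replace = TRUE)
    )
  })
  expect_equal(tidy(run_ewas(beta, pheno, svs = NULL)),
               tidy(run_ewas(beta, pheno)))
})

test_that("consistent sample relabelling leaves estimates unchanged", {
  withr::with_seed(8, {
    beta <- make_beta(runif(500), 25, 20)
    pheno <- tibble::tibble(
      sample_id = colnames(beta),
      condition = rep(c(0L, 1L), 10),
      age = sample(c(15L, 17L), 20, replace = TRUE)
    )
    perm <- sample(20)
  })
  r1 <- tidy(run_ewas(beta, pheno))
  r2 <- tidy(run_ewas(beta[, perm], pheno[perm, ]))
  expect_equal(r1, r2)
})

test_that("lambda identities hold", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1)
  ok <- vapply(1:10, function(s) {
    p <- withr::with_seed(s, runif(10000))
    l <- genomic_lambda(p)
    l >= 0.95 && l <= 1.05
  }, logical(1))
  expect_gte(sum(ok), 9)
  withr::with_seed(6, p <- runif(500))
  expect_gt(genomic_lambda(p / 2), genomic_lambda(p))
  expect_error(genomic_lambda(runif(50)), "100")
})

test_that("hit selection is strictly below threshold with ordered ties", {
  res <- tibble::tibble(
    probe_id = c("b", "a", "c", "d"),
    p = c(1e-6, 1e-6, 1e-5, 0.5)
  )
  expect_equal(select_hits(res, threshold = 1e-5), c("a", "b"))
  expect_equal(select_hits(res[0, ], threshold = 1e-5), character(0))
})

test_that("qq pairs use rank/(m+1) expectations", {
  q1 <- qq_data(0.5)
  expect_equal(q1$expected, -log10(0.5))
  expect_equal(q1$observed, -log10(0.5))
  withr::with_seed(2, p <- runif(1e5))
  q <- qq_data(p)
  expect_equal(nrow(q), length(p))
  # Glivenko-Cantelli: observed quantiles approach uniform expectations
  expect_lt(max(abs(q$observed_p - q$expected_p)), 0.01)
  expect_error(qq_data(numeric(0)), "at least one")
})
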