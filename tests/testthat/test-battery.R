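test_that("summary percentages use the full-group denominator", {
  pheno <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    cond = rep(c(1L, 0L), each = 10),
    xbin = c(rep(1L, 6), rep(0L, 2), NA, NA, rep(0L, 10))
  )
  s <- summarize_phenotypes(pheno, "cond", "xbin")
  case_row <- s[s$group == "case", ]
  expect_equal(case_row$n_positive, 6)
  expect_equal(case_row$pct, 60)        # 6/10, missing included in denominator
  expect_equal(case_row$n_missing, 2)
  ctrl_row <- s[s$group == "control", ]
  expect_equal(ctrl_row$label, "0 (0.0)")
  expect_error(summarize_phenotypes(pheno, "nope", "xbin"), "condition")
})

test_that("eligibility applies the strictly-fewer-than-five rule per cell", {
  mk <- function(cells) {
    # cells = c(exposed cases, exposed controls, unexposed cases, unexposed ctrl)
    tibble::tibble(
      cond = rep(c(1L, 0L, 1L, 0L), cells),
      x = rep(c(1L, 1L, 0L, 0L), cells)
    )
  }
  bad <- eligibility(mk(c(100, 50, 4, 80)), "x", "cond")
  expect_false(bad$eligible)
  expect_match(bad$reason, "unexposed_cases")
  expect_true(eligibility(mk(c(5, 5, 5, 5)), "x", "cond")$eligible)
  expect_true(eligibility(mk(c(100, 50, 5, 80)), "x", "cond")$eligible)
  # continuous: non-missing count per group
  cont <- tibble::tibble(cond = rep(c(1L, 0L), c(4, 50)),
                         z = rnorm(54))
  expect_false(eligibility(cont, "z", "cond")$eligible)
  expect_error(eligibility(cont, "missing_var", "cond"), "declared")
})

test_that("z-scoring is exact, idempotent and shift/scale invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(3, x <- c(rnorm(50), NA, NA))
  z <- zscore(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z[!is.na(z)]), 1, tolerance = 1e-12)
  expect_equal(which(is.na(z)), which(is.na(x)))
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_equal(zscore(3 + 2 * x), z, tolerance = 1e-12)
  expect_error(zscore(c(5, 5, 5)), "zero")
  expect_error(zscore(c(1, NA)), "non-missing")
})

test_that("logistic OR on a 2x2 equals the cross-product ratio", {
  tab <- tibble::tibble(
    cond = rep(c(1L, 0L, 1L, 0L), c(20, 10, 10, 20)),
    x = rep(c(1L, 1L, 0L, 0L), c(20, 10, 10, 20))
  )
  got <- logistic_test(tab, "x", "cond")
  expect_equal(got$odds_ratio, 4, tolerance = 1e-8)
  expect_equal(got$n, 60)
  balanced <- tibble::tibble(
    cond = rep(c(1L, 0L, 1L, 0L), each = 25),
    x = rep(c(1L, 1L, 0L, 0L), each = 25)
  )
  got_b <- logistic_test(balanced, "x", "cond")
  expect_equal(got_b$odds_ratio, 1, tolerance = 1e-8)
  expect_gt(got_b$p, 0.99)
})

test_that("random 2x2 tables match the cross-product within 1e-8", {
  withr::with_seed(11, {
    for (i in 1:20) {
      cells <- sample(5:40, 4, replace = TRUE)
      tab <- tibble::tibble(
        cond = rep(c(1L, 0L, 1L, 0L), cells),
        x = rep(c(1L, 1L, 0L, 0L), cells)
      )
      got <- logistic_test(tab, "x", "cond")
      expect_equal(got$odds_ratio,
                   (cells[1] * cells[4]) / (cells[2] * cells[3]),
                   tolerance = 1e-8)
    }
  })
})

test_that("continuous-exposure fits match the Newton-Raphson oracle", {
  withr::with_seed(21, {
    for (i in 1:5) {
      n <- 60
      x <- rnorm(n)
      y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
      pheno <- tibble::tibble(cond = y, x = x)
      got <- logistic_test(pheno, "x", "cond")
      want <- logistic_oracle(y, zscore(x))
      expect_equal(log(got$odds_ratio), want$coef[2], tolerance = 1e-8)
      expect_equal(log(got$ci_high) - log(got$odds_ratio),
                   qnorm(0.975) * want$se[2], tolerance = 1e-6)
    }
  })
})

test_that("adjusted fits include the adjusters and match the oracle", {
  withr::with_seed(31, {
    n <- 120
    sep <- rbinom(n, 1, 0.4)
    aam <- rnorm(n, 150, 12)
    x <- rnorm(n) + 0.5 * sep
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * x + 0.4 * sep))
    pheno <- tibble::tibble(cond = y, x = x, sep = sep, aam_months = aam)
    got <- logistic_test(pheno, "x", "cond", adjusters = c("sep", "aam_months"))
    want <- logistic_oracle(y, cbind(zscore(x), sep, aam))
    expect_equal(log(got$odds_ratio), want$coef[2], tolerance = 1e-8)
    expect_equal(got$model, "adjusted")
  })
})

test_that("perfect separation is flagged without estimates", {
  sep_tab <- tibble::tibble(cond = rep(c(1L, 0L), each = 20),
                            x = rep(c(1L, 0L), each = 20))
  got <- logistic_test(sep_tab, "x", "cond")
  expect_true(got$omitted)
  expect_match(got$reason, "separation")
  one_class <- tibble::tibble(cond = rep(1L, 20), x = rbinom(20, 1, 0.5))
  expect_true(logistic_test(one_class, "x", "cond")$omitted)
})

test_that("independent adjusters leave the OR essentially unchanged", {
  withr::with_seed(41, {
    n <- 4000
    x <- rnorm(n)
    sep <- rbinom(n, 1, 0.5)          # independent of x and y
    aam <- rnorm(n, 150, 12)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
    pheno <- tibble::tibble(cond = y, x = x, sep = sep, aam_months = aam)
    unadj <- logistic_test(pheno, "x", "cond")
    adj <- logistic_test(pheno, "x", "cond", adjusters = c("sep", "aam_months"))
    expect_equal(log(adj$odds_ratio), log(unadj$odds_ratio), tolerance = 0.05)
  })
})

test_that("the battery maps traits, reports unmapped ones and runs a-priori", {
  withr::with_seed(51, {
    n <- 300
    conf <- rnorm(n)
    cond <- rbinom(n, 1, plogis(-1 + conf))
    pheno <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:n), condition = cond,
      smoke_score = conf + rnorm(n, sd = 0.3),
      bmi = rnorm(n, 17, 2),
      sep = rbinom(n, 1, 0.3), aam_months = rnorm(n, 150, 12)
    )
  })
  hyp <- tibble::tibble(trait = c("Smoking", "primary Sjögren's syndrome"))
  vmap <- tibble::tibble(trait = "smoking", variable = "smoke_score")
  out <- run_battery(pheno, hyp, vmap, conditions = "condition",
                     a_priori = "bmi")
  expect_setequal(unique(out$exposure), c("smoke_score", "bmi"))
  expect_equal(attr(out, "unmapped"), "primary Sjögren's syndrome")
  expect_setequal(out$model[out$exposure == "smoke_score"],
                  c("unadjusted", "adjusted"))
  # planted positive confounder association shows OR > 1
  or <- out$odds_ratio[out$exposure == "smoke_score" &
                         out$model == "unadjusted"]
  expect_gt(or, 1)

  # empty hypothesis set: only the a-priori variables run
  empty_h <- tibble::tibble(trait = character(0))
  out2 <- run_battery(pheno, empty_h, vmap, conditions = "condition",
                      a_priori = c("smoke_score", "bmi"))
  expect_setequal(unique(out2$exposure), c("smoke_score", "bmi"))
})

test_that("the planted confounder's OR direction matches the planted sign", {
  signs <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_config(n_samples = 500, n_probes = 10,
                                     n_direct_probes = 0,
                                     n_confounded_probes = 0,
                                     n_batch_probes = 0, seed = s))
    got <- logistic_test(d$pheno, "confounder", "condition")
    got$odds_ratio > 1   # planted log-odds is +1 per confounder unit
  }, logical(1))
  expect_gte(sum(signs), 9)
})
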