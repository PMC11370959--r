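#' Ordinary least squares for a single probe
#'
#' Complete-case OLS of one probe's methylation on the design matrix; the
#' reported effect is the case-status coefficient (difference in beta-value
#' units associated with case status), with t-based two-sided p-value and
#' Wald 95% CI on n - k degrees of freedom. Probes with zero residual
#' variance are flagged degenerate (no p-value); rank-deficient complete-case
#' designs are skipped with a reason.
#'
#' @param y Numeric vector of per-sample beta values (missing allowed).
#' @param design Numeric design matrix (samples x k) whose column named
#'   `case` carries the exposure; surrogate variables are simply extra
#'   columns.
#' @return One-row tibble: `beta`, `se`, `ci_low`, `ci_high`, `p`, `n`,
#'   `degenerate`, `skipped`, `reason`.
#' @export
fit_probe <- function(y, design) {
  cc <- !is.na(y) & stats::complete.cases(design)
  n <- sum(cc)
  k <- ncol(design)
  empty <- tibble::tibble(
    beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, n = n, degenerate = FALSE, skipped = TRUE,
    reason = NA_character_
  )
  if (n <= k) {
    empty$reason <- "complete-case subset no larger than design"
    return(empty)
  }
  x <- design[cc, , drop = FALSE]
  yy <- y[cc]
  qx <- qr(x)
  if (qx$rank < k) {
    empty$reason <- "rank-deficient design on complete cases"
    return(empty)
  }
  coefs <- qr.coef(qx, yy)
  res <- qr.resid(qx, yy)
  rss <- sum(res^2)
  est <- coefs[["case"]]
  if (rss <= 1e-16 * sum(yy^2) + 1e-30) {
    return(tibble::tibble(
      beta = est, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p = NA_real_, n = n, degenerate = TRUE, skipped = FALSE,
      reason = "zero residual variance"
    ))
  }
  sigma2 <- rss / (n - k)
  xtxi <- chol2inv(qr.R(qx))
  case_idx <- which(colnames(x) == "case")
  se <- sqrt(sigma2 * xtxi[case_idx, case_idx])
  tval <- est / se
  crit <- qt(0.975, n - k)
  tibble::tibble(
    beta = est, se = se,
    ci_low = est - crit * se, ci_high = est + crit * se,
    p = 2 * pt(-abs(tval), n - k),
    n = n, degenerate = FALSE, skipped = FALSE, reason = NA_character_
  )
}

# One-shot OLS across all complete probes sharing the design; numerically
# identical to fit_probe, vastly faster for a full scan.
fit_probes_complete <- function(ymat, design) {
  n <- nrow(design)
  k <- ncol(design)
  qx <- qr(design)
  coefs <- qr.coef(qx, t(ymat))           # k x m
  resid <- qr.resid(qx, t(ymat))          # n x m
  rss <- unname(colSums(resid^2))
  sigma2 <- rss / (n - k)
  xtxi <- chol2inv(qr.R(qx))
  case_idx <- which(colnames(design) == "case")
  est <- unname(coefs[case_idx, ])
  se <- unname(sqrt(sigma2 * xtxi[case_idx, case_idx]))
  degenerate <- unname(rss <= 1e-16 * colSums(t(ymat)^2) + 1e-30)
  tval <- est / se
  crit <- qt(0.975, n - k)
  out <- tibble::tibble(
    probe_id = rownames(ymat),
    beta = est, se = se,
    ci_low = est - crit * se, ci_high = est + crit * se,
    p = 2 * pt(-abs(tval), n - k),
    n = n, degenerate = degenerate, skipped = FALSE, reason = NA_character_
  )
  out$se[degenerate] <- NA_real_
  out$ci_low[degenerate] <- NA_real_
  out$ci_high[degenerate] <- NA_real_
  out$p[degenerate] <- NA_real_
  out$reason[degenerate] <- "zero residual variance"
  out
}

#' Run the mass-univariate methylation scan
#'
#' Fits [fit_probe()] for every probe with case status as the exposure and
#' methylation as the outcome, adjusted for age at measurement and any
#' supplied surrogate variables — nothing else, by design: the minimally
#' adjusted scan deliberately leaves confounded signal in so the catalog
#' look-up can harvest it. Only case and control samples enter; less-severe
#' and excluded samples are dropped.
#'
#' @param beta Numeric beta matrix, probes x samples.
#' @param pheno Phenotype tibble with `sample_id` and the age column.
#' @param status Optional status tibble from [derive_status()]; if supplied,
#'   case status is status == "case" vs "control". Otherwise `pheno` must
#'   already contain the 0/1 column named by `case`.
#' @param svs Optional `sv_set` from [compute_svs()] (or a bare numeric
#'   matrix of surrogate variables, samples x k).
#' @param case,age Column names in `pheno`.
#' @param threshold Suggestive hit threshold recorded on the result
#'   (default 1e-5).
#' @return An `ewas_result` object; `tidy()` gives the per-probe table
#'   (sorted by p, ties broken by probe id), `glance()` the scan-level
#'   summary including the genomic inflation factor lambda.
#' @export
run_ewas <- function(beta, pheno, status = NULL, svs = NULL,
                     case = "condition", age = "age", threshold = 1e-5) {
  assert_beta_matrix(beta)
  pheno <- tibble::as_tibble(pheno)

  if (!is.null(status)) {
    st <- status[status$status %in% c("case", "control"), ]
    pheno <- pheno[match(st$sample_id, pheno$sample_id), ]
    pheno[[case]] <- as.integer(st$status == "case")
    pheno <- pheno[!is.na(pheno$sample_id), ]
  }
  keep <- intersect(colnames(beta), pheno$sample_id)
  keep <- keep[!is.na(pheno[[case]][match(keep, pheno$sample_id)])]
  if (length(keep) < 10) {
    abort("fewer than 10 usable case/control samples.")
  }
  beta <- beta[, keep, drop = FALSE]
  pheno <- pheno[match(keep, pheno$sample_id), ]

  design <- build_design(pheno, case = case, age = age)
  if (!is.null(svs)) {
    svm <- if (inherits(svs, "sv_set")) svs$sv else as.matrix(svs)
    if (!is.null(rownames(svm))) svm <- svm[keep, , drop = FALSE]
    design <- cbind(design, svm)
  }
  n_sv <- ncol(design) - sum(colnames(design) %in% c("intercept", "case", "age"))

  has_na <- rowSums(is.na(beta)) > 0
  res_complete <- if (any(!has_na)) {
    fit_probes_complete(beta[!has_na, , drop = FALSE], design)
  }
  res_missing <- if (any(has_na)) {
    purrr::map_dfr(which(has_na), function(i) {
      dplyr::bind_cols(tibble::tibble(probe_id = rownames(beta)[i]),
                       fit_probe(beta[i, ], design))
    })
  }
  results <- dplyr::bind_rows(res_complete, res_missing) |>
    dplyr::arrange(.data$p, .data$probe_id)

  p_ok <- results$p[!is.na(results$p)]
  lambda <- if (length(p_ok) >= 100) genomic_lambda(p_ok) else NA_real_

  structure(
    list(
      results = results,
      lambda = lambda,
      n_samples = length(keep),
      covariates = setdiff(colnames(design), "intercept"),
      n_sv = n_sv,
      threshold = threshold
    ),
    class = "ewas_result"
  )
}

#' Genomic inflation factor
#'
#' Lambda = median of the chi-square(1) quantiles of the observed p-values
#' divided by the null median of chi-square(1) (about 0.4549). Lambda near 1
#' indicates calibrated tests; planted batch structure inflates it, and
#' surrogate-variable adjustment should pull it back toward 1.
#'
#' @param p_values Numeric vector of p-values; at least 100 non-missing.
#' @return Lambda (scalar).
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 100) abort("genomic lambda needs >= 100 non-missing p-values.")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Select suggestive hits from a scan
#'
#' Probes with p strictly below the threshold (default 1e-5; a probe at
#' exactly the threshold is excluded), sorted by ascending p with ties broken
#' by probe id.
#'
#' @param result An `ewas_result` or its tidy per-probe tibble.
#' @param threshold P-value cut; strictly-below rule.
#' @return Character vector of probe ids.
#' @export
select_hits <- function(result, threshold = NULL) {
  tbl <- if (inherits(result, "ewas_result")) result$results else result
  threshold <- threshold %||%
    (if (inherits(result, "ewas_result")) result$threshold else 1e-5)
  hit <- tbl[!is.na(tbl$p) & tbl$p < threshold, ]
  hit <- hit[order(hit$p, hit$probe_id), ]
  hit$probe_id
}

#' Expected-vs-observed quantile pairs for a QQ plot
#'
#' Observed p-values sorted ascending, paired with uniform expectations
#' rank/(m + 1); both returned on the -log10 scale alongside the raw pairs.
#'
#' @param p_values Numeric vector of p-values (>= 1).
#' @return Tibble: `expected_p`, `observed_p`, `expected`, `observed`
#'   (the last two are -log10 values).
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) abort("qq_data needs at least one p-value.")
  obs <- sort(p)
  m <- length(obs)
  expd <- seq_len(m) / (m + 1)
  tibble::tibble(
    expected_p = expd, observed_p = obs,
    expected = -log10(expd), observed = -log10(obs)
  )
}

#' @export
print.ewas_result <- function(x, ...) {
  cat(sprintf(
    "<ewas_result> %d probes, %d samples, covariates: %s\n",
    nrow(x$results), x$n_samples, paste(x$covariates, collapse = " + ")
  ))
  cat(sprintf("  lambda = %s, threshold = %g, hits = %d\n",
              ifelse(is.na(x$lambda), "NA", sprintf("%.3f", x$lambda)),
              x$threshold, length(select_hits(x))))
  print(head(x$results, 5))
  invisible(x)
}
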