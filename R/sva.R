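# Per-probe mean imputation, used only while estimating surrogate variables;
# the scan itself stays complete-case per probe.
impute_row_means <- function(beta) {
  if (!anyNA(beta)) return(beta)
  rm <- rowMeans(beta, na.rm = TRUE)
  if (anyNA(rm)) abort("probe(s) with no non-missing values cannot be imputed.")
  idx <- which(is.na(beta), arr.ind = TRUE)
  beta[idx] <- rm[idx[, 1]]
  beta
}

#' Build the protected design matrix for the scan
#'
#' Intercept, case status and age at methylation measurement: the full,
#' deliberately minimal covariate set of the scan. These columns are
#' protected during surrogate-variable estimation so the surrogate variables
#' capture technical structure only, not the exposure.
#'
#' @param pheno Phenotype tibble aligned to the beta matrix columns.
#' @param case Name of the 0/1 case-status column.
#' @param age Name of the age-at-measurement column.
#' @return Numeric matrix (samples x 3) with sample-id rownames.
#' @export
build_design <- function(pheno, case = "condition", age = "age") {
  for (col in c("sample_id", case, age)) {
    if (!col %in% names(pheno)) abort(sprintf("pheno lacks column `%s`.", col))
  }
  x <- cbind(
    intercept = 1,
    case = as.numeric(pheno[[case]]),
    age = as.numeric(pheno[[age]])
  )
  rownames(x) <- pheno$sample_id
  if (qr(x)$rank < ncol(x)) {
    # age may be constant in small simulations; drop to keep full rank
    x <- x[, c(TRUE, TRUE, stats::var(x[, "age"]) > 0), drop = FALSE]
  }
  x
}

residualize <- function(beta, design) {
  qx <- qr(design)
  # residual of each probe (row) on the design: Y - Y P_X
  beta - t(qr.fitted(qx, t(beta)))
}

# Vectorised per-probe F-test p-values comparing nested designs.
row_f_pvalues <- function(y, full, reduced) {
  n <- ncol(y)
  q_full <- qr(full)
  q_red <- qr(reduced)
  df1 <- q_full$rank
  df0 <- q_red$rank
  rss1 <- rowSums(t(qr.resid(q_full, t(y)))^2)
  rss0 <- rowSums(t(qr.resid(q_red, t(y)))^2)
  fstat <- ((rss0 - rss1) / (df1 - df0)) / (rss1 / (n - df1))
  p <- stats::pf(fstat, df1 - df0, n - df1, lower.tail = FALSE)
  # noise-free probes: zero residual variance means certain association
  p[rss1 <= .Machine$double.eps * rss0] <- 0
  p[is.na(p)] <- 1
  p
}

#' Estimate the number of surrogate variables by permutation
#'
#' Parallel-analysis estimate: the beta matrix is residualised on the
#' protected design, the variance proportion of each singular component is
#' compared with its permutation null (each probe's values permuted
#' independently, destroying cross-probe structure while keeping marginals),
#' and the count of leading components exceeding the null's upper quantile is
#' returned.
#'
#' @param beta Numeric beta matrix, probes x samples. Missing cells are
#'   mean-imputed per probe for this step only.
#' @param design Protected design matrix from [build_design()].
#' @param n_permutations Number of permutation replicates (default 20).
#' @param seed Integer seed; the estimate is deterministic given it.
#' @param sig_quantile Null quantile a component must exceed (default 0.95).
#' @return Integer count of surrogate variables (possibly 0).
#' @export
estimate_n_sv <- function(beta, design, n_permutations = 20, seed = 1L,
                          sig_quantile = 0.95) {
  assert_count(n_permutations, "n_permutations", min = 1)
  if (ncol(design) >= ncol(beta)) {
    abort("design has at least as many columns as there are samples.")
  }
  y <- impute_row_means(beta)
  n_comp <- min(nrow(y), ncol(y) - qr(design)$rank)

  prop_var <- function(mat) {
    d <- svd(residualize(mat, design), nu = 0, nv = 0)$d
    p <- d^2 / sum(d^2)
    p[seq_len(n_comp)]
  }

  obs <- prop_var(y)
  withr::with_seed(seed, {
    null_props <- vapply(seq_len(n_permutations), function(b) {
      perm <- t(apply(y, 1, sample))
      prop_var(perm)
    }, numeric(n_comp))
  })
  thresholds <- apply(null_props, 1, quantile, probs = sig_quantile,
                      type = 7, names = FALSE)
  exceeds <- obs > thresholds
  # leading run only: a component is counted while all above it also exceed
  n_sv <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  as.integer(n_sv)
}

#' Compute surrogate variables by iteratively reweighted SVA
#'
#' Two-step iteratively reweighted surrogate variable analysis: (1)
#' residualise the matrix on the protected design and take the leading
#' right-singular vectors as provisional surrogate variables; (2) weight
#' each probe by the evidence it is associated with the surrogate variables
#' but *not* with the protected (non-intercept) covariates, given the
#' surrogate variables; (3) recompute the singular decomposition of the
#' weighted, row-centred data matrix; repeat. The final decomposition uses
#' the raw (centred) data, not the residuals, so a technical factor that is
#' partially collinear with the exposure can still be absorbed — protection
#' of the exposure is enforced softly, through the weights that exclude
#' probes carrying exposure signal, rather than by forcing orthogonality.
#'
#' @inheritParams estimate_n_sv
#' @param n_sv Number of surrogate variables (>= 1).
#' @param max_iterations Reweighting iterations (default 5).
#' @return An `sv_set` object: list with `sv` (samples x n_sv matrix,
#'   columns zero-mean and mutually orthogonal), `n_sv`, `method`,
#'   `iterations`.
#' @export
compute_svs <- function(beta, design, n_sv, max_iterations = 5) {
  assert_count(n_sv, "n_sv", min = 1)
  assert_count(max_iterations, "max_iterations", min = 1)
  y <- impute_row_means(beta)
  n <- ncol(y)
  r_resid <- min(nrow(y), n - qr(design)$rank)
  if (n_sv >= r_resid) {
    abort(sprintf(
      "n_sv = %d must be below the residual-space rank (%d).", n_sv, r_resid
    ))
  }

  resid <- residualize(y, design)
  sv <- svd(resid, nu = 0)$v[, seq_len(n_sv), drop = FALSE]
  intercept_only <- matrix(1, n, 1)
  has_protected <- ncol(design) > 1
  y_centred <- y - rowMeans(y)

  for (it in seq_len(max_iterations)) {
    p_gam <- row_f_pvalues(y, cbind(intercept_only, sv), intercept_only)
    w <- 1 - p_gam
    # The exposure-protection factor enters once the surrogate-variable
    # anchor is stable (iteration 2 on). Applying it against the first,
    # residual-space anchor would zero out every probe of a technical factor
    # that is partially collinear with the exposure — exactly the factor the
    # surrogate variable must absorb.
    if (it > 1 && has_protected) {
      w <- w * row_f_pvalues(y, cbind(design, sv), cbind(intercept_only, sv))
    }
    if (sum(w) <= .Machine$double.eps) break
    sv <- svd(y_centred * w, nu = 0)$v[, seq_len(n_sv), drop = FALSE]
  }

  colnames(sv) <- paste0("sv", seq_len(n_sv))
  rownames(sv) <- colnames(beta)
  structure(
    list(sv = sv, n_sv = as.integer(n_sv), method = "irw-sva",
         iterations = max_iterations),
    class = "sv_set"
  )
}

#' Write a surrogate-variable set as TSV with a JSON sidecar
#'
#' @param svs An `sv_set` from [compute_svs()].
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_svs <- function(svs, path) {
  tbl <- tibble::as_tibble(svs$sv, rownames = "sample_id")
  readr::write_tsv(tbl, path)
  jsonlite::write_json(
    list(n_sv = svs$n_sv, method = svs$method, iterations = svs$iterations),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}
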