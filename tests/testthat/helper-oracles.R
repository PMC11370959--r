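# Independent oracles, deliberately written with different machinery than the
# implementation: normal equations + explicit t-distribution for OLS,
# Newton-Raphson for the logistic MLE, choose()-arithmetic enumeration for
# the exact 2x2 test.

# OLS oracle: solve(t(X) X) directly, never QR.
ols_oracle <- function(y, x, coef_idx = 2) {
  keep <- !is.na(y) & stats::complete.cases(x)
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(x)
  xtx_inv <- solve(t(x) %*% x)
  b <- xtx_inv %*% t(x) %*% y
  res <- y - x %*% b
  sigma2 <- sum(res^2) / (n - k)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- b / se
  list(
    beta = unname(b[coef_idx]),
    se = unname(se[coef_idx]),
    p = unname(2 * stats::pt(-abs(tval[coef_idx]), n - k)),
    ci_low = unname(b[coef_idx] - stats::qt(0.975, n - k) * se[coef_idx]),
    ci_high = unname(b[coef_idx] + stats::qt(0.975, n - k) * se[coef_idx])
  )
}

# Logistic MLE oracle: Newton-Raphson on the log-likelihood score.
logistic_oracle <- function(y, x, tol = 1e-12, max_iter = 100) {
  x <- cbind(1, x)
  b <- rep(0, ncol(x))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(x %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- t(x) %*% (y - mu)
    info <- t(x) %*% (x * w)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(x %*% b)
  mu <- 1 / (1 + exp(-eta))
  info <- t(x) %*% (x * (mu * (1 - mu)))
  list(coef = as.vector(b), se = unname(sqrt(diag(solve(info)))))
}

# Two-sided Fisher exact oracle: enumerate the hypergeometric support with
# choose() arithmetic and sum probabilities no larger than the observed one
# (with the conventional relative fudge for float ties).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # hits
  n_other <- c + d    # non-hits
  k <- a + c          # trait-annotated
  lo <- max(0, k - n_other)
  hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n_other, k - support) -
    lchoose(m + n_other, k)
  prob <- exp(logp)
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# tiny named beta matrix builder
make_beta <- function(values, n_probes, n_samples) {
  m <- matrix(values, nrow = n_probes, ncol = n_samples)
  dimnames(m) <- list(sprintf("cg%07d", seq_len(n_probes)),
                      sprintf("S%03d", seq_len(n_samples)))
  m
}

make_annotation <- function(probe_ids, chr = "1", gene = "", class = "cpg",
                            detection_fail = 0L, chen_flag = 0L) {
  tibble::tibble(
    probe_id = probe_ids,
    chr = rep_len(chr, length(probe_ids)),
    pos = seq_along(probe_ids) * 100L,
    gene = rep_len(gene, length(probe_ids)),
    class = rep_len(class, length(probe_ids)),
    detection_fail = rep_len(detection_fail, length(probe_ids)),
    chen_flag = rep_len(chen_flag, length(probe_ids))
  )
}

dys_hits <- c("cg08142094", "cg23012731", "cg21802726", "cg04583842",
              "cg22603569", "cg04737758", "cg15017604")
hmb_hits <- c("cg24196053", "cg11465939")
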