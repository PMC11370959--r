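#' @importFrom rlang .data abort warn %||%
#' @importFrom stats median pnorm pt qchisq qlogis qnorm qt quantile rbinom
#'   rnorm runif sd setNames plogis glm binomial coef vcov fisher.test
#'   complete.cases pf var
#' @importFrom utils head
NULL

# Round half away from zero at `digits` decimals. base round() rounds half to
# even, which disagrees with the convention used in printed cohort tables
# (e.g. 22.25 -> 22.3, not 22.2).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalise a trait name for deduplication
#'
#' Trims, collapses internal whitespace and case-folds. Catalog dumps mix
#' capitalisations of the same trait ("Smoking" / "smoking"); all trait
#' comparisons in the package go through this normal form.
#'
#' @param x Character vector of trait names.
#' @return Character vector of normalised names.
#' @export
normalize_trait <- function(x) {
  x <- stringr::str_squish(x)
  tolower(x)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# per-component streams without reuse. Kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 2011L
}

# shared validation helpers ---------------------------------------------------

assert_beta_matrix <- function(mat, arg = "beta") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort(sprintf("`%s` must be a numeric matrix (probes x samples).", arg))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort(sprintf("`%s` must have probe rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(mat))) abort("probe ids must be unique.")
  if (anyDuplicated(colnames(mat))) abort("sample ids must be unique.")
  rng <- range(mat, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort(sprintf("`%s` has values outside [0, 1]; beta-values required.", arg))
  }
  invisible(mat)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
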