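infer_type <- function(x) {
  v <- x[!is.na(x)]
  if (all(v %in% c(0, 1))) "binary" else "continuous"
}

#' Summarise candidate phenotypes by case/control group
#'
#' Cohort-table style summary: for binary variables the positive count and
#' percentage, for continuous variables the mean and SD over non-missing
#' values, plus the per-group missing count. Percentages use the *total*
#' group size (missing included) as denominator — the convention of the
#' published table this reproduces (445/641 = 69.4%). Percentages and
#' moments are rounded half-up to one decimal in the `label` column; the
#' unrounded values are also returned.
#'
#' @param pheno Phenotype tibble with a 0/1/`NA` condition column.
#' @param condition Name of the condition column (e.g. "dysmenorrhea").
#' @param variables Variables to summarise; default every column that is not
#'   an id or condition column. A declaration tibble like
#'   [table1_variables()] (columns `variable`, `type`) is also accepted.
#' @return Tibble: `variable`, `type`, `group`, `n_group`, `n_missing`,
#'   `n_positive`, `pct`, `mean`, `sd`, `label`.
#' @export
summarize_phenotypes <- function(pheno, condition, variables = NULL) {
  pheno <- tibble::as_tibble(pheno)
  if (!condition %in% names(pheno)) {
    abort(sprintf("unknown condition column `%s`.", condition))
  }
  if (is.null(variables)) {
    variables <- setdiff(names(pheno),
                         c("sample_id", condition, "dysmenorrhea", "hmb"))
  }
  decl <- if (is.data.frame(variables)) variables else
    tibble::tibble(variable = variables, type = NA_character_)

  groups <- list(case = 1L, control = 0L)
  purrr::map_dfr(seq_len(nrow(decl)), function(i) {
    v <- decl$variable[i]
    if (!v %in% names(pheno)) {
      abort(sprintf("variable `%s` not present in pheno.", v))
    }
    type <- decl$type[i]
    if (is.na(type)) type <- infer_type(pheno[[v]])
    purrr::map_dfr(names(groups), function(g) {
      x <- pheno[[v]][!is.na(pheno[[condition]]) &
                        pheno[[condition]] == groups[[g]]]
      n_group <- length(x)
      n_missing <- sum(is.na(x))
      if (type == "binary") {
        n_pos <- sum(x == 1, na.rm = TRUE)
        pct <- 100 * n_pos / n_group
        tibble::tibble(
          variable = v, type = type, group = g,
          n_group = n_group, n_missing = n_missing,
          n_positive = n_pos, pct = pct,
          mean = NA_real_, sd = NA_real_,
          label = sprintf("%d (%.1f)", n_pos, round_half_up(pct, 1))
        )
      } else {
        mu <- mean(x, na.rm = TRUE)
        s <- sd(x[!is.na(x)])
        tibble::tibble(
          variable = v, type = type, group = g,
          n_group = n_group, n_missing = n_missing,
          n_positive = NA_integer_, pct = NA_real_,
          mean = mu, sd = s,
          label = sprintf("%.1f (%.1f)",
                          round_half_up(mu, 1), round_half_up(s, 1))
        )
      }
    })
  })
}

#' Screen a variable for adequate cell counts
#'
#' A binary exposure is ineligible when any cell of its non-missing
#' exposure-by-condition 2x2 has fewer than `min_cell` participants
#' (strictly fewer: cells of exactly `min_cell` pass); a continuous exposure
#' is ineligible when cases or controls have fewer than `min_cell`
#' non-missing values.
#'
#' @param pheno Phenotype tibble.
#' @param variable Exposure column name.
#' @param condition Condition column name (0/1/`NA`).
#' @param min_cell Minimum per-cell count (default 5).
#' @return One-row tibble: `variable`, `eligible`, `reason`.
#' @export
eligibility <- function(pheno, variable, condition, min_cell = 5) {
  if (!variable %in% names(pheno)) {
    abort(sprintf("variable `%s` not declared in pheno.", variable))
  }
  x <- pheno[[variable]]
  y <- pheno[[condition]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  type <- infer_type(x)
  if (type == "binary") {
    cells <- c(
      exposed_cases = sum(x == 1 & y == 1),
      exposed_controls = sum(x == 1 & y == 0),
      unexposed_cases = sum(x == 0 & y == 1),
      unexposed_controls = sum(x == 0 & y == 0)
    )
    sparse <- cells < min_cell
    if (any(sparse)) {
      return(tibble::tibble(
        variable = variable, eligible = FALSE,
        reason = sprintf("cell(s) below %d participants: %s", min_cell,
                         paste(names(cells)[sparse], collapse = ", "))
      ))
    }
  } else {
    n_case <- sum(y == 1)
    n_ctrl <- sum(y == 0)
    if (n_case < min_cell || n_ctrl < min_cell) {
      return(tibble::tibble(
        variable = variable, eligible = FALSE,
        reason = sprintf(
          "fewer than %d non-missing %s", min_cell,
          paste(c("cases", "controls")[c(n_case, n_ctrl) < min_cell],
                collapse = " and ")
        )
      ))
    }
  }
  tibble::tibble(variable = variable, eligible = TRUE, reason = NA_character_)
}

#' Standardise a continuous vector to z-scores
#'
#' Mean 0, SD 1 over non-missing entries; missing values preserved.
#' Standardisation happens within whatever sample is passed in, so callers
#' fitting complete-case models standardise within each model's analysis
#' sample.
#'
#' @param values Numeric vector.
#' @return Standardised numeric vector.
#' @export
zscore <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) abort("zscore needs >= 2 non-missing values.")
  s <- sd(v)
  if (s == 0) abort("zero standard deviation: variable cannot be z-scored.")
  (values - mean(v)) / s
}

#' Logistic regression of the condition on one exposure
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`) of case status on the exposure plus any adjusters,
#' complete-case on the model's variables. Continuous exposures are z-scored
#' within the analysis sample so odds ratios are per SD. Wald 95% CI and
#' two-sided Wald p on the log-odds scale. Perfect separation or
#' non-convergence is flagged and no estimate is reported.
#'
#' @param pheno Phenotype tibble.
#' @param exposure Exposure column name.
#' @param condition Condition column name (0/1/`NA`).
#' @param adjusters Character vector of adjustment column names (e.g. a
#'   socioeconomic-position indicator and age at menarche in months).
#' @return One-row tibble: `exposure`, `condition`, `model`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p`, `n`, `omitted`, `reason`.
#' @export
logistic_test <- function(pheno, exposure, condition,
                          adjusters = character()) {
  model_label <- if (length(adjusters)) "adjusted" else "unadjusted"
  omit <- function(reason, n = NA_integer_) tibble::tibble(
    exposure = exposure, condition = condition, model = model_label,
    odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, n = n, omitted = TRUE, reason = reason
  )
  cols <- c(exposure, condition, adjusters)
  miss <- setdiff(cols, names(pheno))
  if (length(miss)) {
    abort(paste0("pheno lacks column(s): ", paste(miss, collapse = ", ")))
  }
  dat <- pheno[stats::complete.cases(pheno[, cols]), cols]
  names(dat)[1:2] <- c(".x", ".y")
  if (!nrow(dat) || length(unique(dat$.y)) < 2) {
    return(omit("outcome does not have both classes on complete cases",
                nrow(dat)))
  }
  if (infer_type(dat$.x) == "continuous") {
    z <- tryCatch(zscore(dat$.x), error = function(e) NULL)
    if (is.null(z)) return(omit("zero variance in exposure", nrow(dat)))
    dat$.x <- z
  } else if (length(unique(dat$.x)) < 2) {
    return(omit("zero variance in exposure", nrow(dat)))
  }

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  b <- unname(coef(fit)[".x"])
  if (separation && abs(b) > 10) {
    return(omit("perfect or quasi-perfect separation", nrow(dat)))
  }
  if (!fit$converged) return(omit("did not converge", nrow(dat)))
  se <- sqrt(vcov(fit)[".x", ".x"])
  z975 <- qnorm(0.975)
  tibble::tibble(
    exposure = exposure, condition = condition, model = model_label,
    odds_ratio = exp(b),
    ci_low = exp(b - z975 * se), ci_high = exp(b + z975 * se),
    p = 2 * pnorm(-abs(b / se)),
    n = nrow(dat), omitted = FALSE, reason = NA_character_
  )
}

#' Run the full hypothesis-testing battery
#'
#' Maps harvested traits to cohort variables, appends any a-priori
#' variables, screens each exposure-condition pair for adequate cell counts,
#' and fits unadjusted and adjusted logistic regressions for the eligible
#' ones. Unmapped traits and ineligible variables appear as omitted rows
#' with a reason, mirroring how omissions are reported alongside estimates.
#'
#' @param pheno Phenotype tibble with the condition columns and exposures.
#' @param hypotheses A `hypothesis_set` from [harvest_traits()] (or a tibble
#'   with a `trait` column).
#' @param variable_map Tibble mapping `trait` to `variable` (cohort column
#'   name); traits are matched after [normalize_trait()].
#' @param conditions Character vector of condition column names.
#' @param adjusters Adjustment columns for the adjusted model.
#' @param a_priori Extra variable names always tested (previously reported
#'   associations).
#' @param min_cell Eligibility threshold (default 5).
#' @return Tibble of association tests, sorted by condition then variable
#'   then model, with attribute `"unmapped"` listing traits that had no
#'   cohort variable.
#' @export
run_battery <- function(pheno, hypotheses, variable_map, conditions,
                        adjusters = c("sep", "aam_months"),
                        a_priori = character(), min_cell = 5) {
  traits <- unique(hypotheses$trait)
  map_norm <- variable_map
  map_norm$trait_norm <- normalize_trait(map_norm$trait)
  matched <- map_norm[match(normalize_trait(traits), map_norm$trait_norm), ]
  unmapped <- traits[is.na(matched$variable)]
  vars <- unique(c(matched$variable[!is.na(matched$variable)], a_priori))

  proto <- tibble::tibble(
    exposure = character(), condition = character(), model = character(),
    odds_ratio = double(), ci_low = double(), ci_high = double(),
    p = double(), n = integer(), omitted = logical(), reason = character()
  )
  rows <- purrr::map_dfr(conditions, function(cond) {
    purrr::map_dfr(sort(vars), function(v) {
      elig <- eligibility(pheno, v, cond, min_cell = min_cell)
      if (!elig$eligible) {
        return(tibble::tibble(
          exposure = v, condition = cond, model = "none",
          odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p = NA_real_, n = NA_integer_, omitted = TRUE,
          reason = elig$reason
        ))
      }
      dplyr::bind_rows(
        logistic_test(pheno, v, cond),
        logistic_test(pheno, v, cond, adjusters = adjusters)
      )
    })
  })
  rows <- dplyr::bind_rows(proto, rows)
  out <- dplyr::arrange(rows, .data$condition, .data$exposure, .data$model)
  attr(out, "unmapped") <- unmapped
  out
}
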