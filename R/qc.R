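#' Read a probe annotation manifest
#'
#' @param path TSV with columns `probe_id`, `chr`, `pos`, `gene`
#'   (semicolon-separated symbols, empty for none), `class`
#'   (cpg/snp/control), `detection_fail` (0/1), `chen_flag` (0/1).
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      chr = readr::col_character(),
      pos = readr::col_integer(),
      gene = readr::col_character(),
      class = readr::col_character(),
      detection_fail = readr::col_integer(),
      chen_flag = readr::col_integer()
    )
  )
  ann$gene[is.na(ann$gene)] <- ""
  if (anyDuplicated(ann$probe_id)) abort("duplicate probe ids in annotation.")
  bad <- setdiff(unique(ann$class), c("cpg", "snp", "control"))
  if (length(bad)) {
    abort(paste0("unknown probe class(es): ", paste(bad, collapse = ", ")))
  }
  ann
}

#' Probe-level filtering of a beta matrix
#'
#' Removes sex-chromosome probes, SNP and control probes, and probes flagged
#' for high detection p-value. Filters are applied in the fixed order
#' sex -> snp/control -> detection, so a probe matching several categories is
#' tallied once, under the first. Retained probe values are untouched.
#'
#' @param beta Numeric beta matrix, probes x samples.
#' @param annotation Annotation tibble covering every matrix probe.
#' @return A list: `beta` (filtered matrix) and `report` — a tibble of the
#'   per-category removal counts (`sex`, `snp_control`, `detection`),
#'   `removed` and `retained`.
#' @export
filter_probes <- function(beta, annotation) {
  assert_beta_matrix(beta)
  unknown <- setdiff(rownames(beta), annotation$probe_id)
  if (length(unknown)) {
    abort(paste0("probes missing from annotation: ",
                 paste(head(unknown, 10), collapse = ", "),
                 if (length(unknown) > 10) ", ..."))
  }
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]

  category <- dplyr::case_when(
    ann$chr %in% c("X", "Y", "chrX", "chrY") ~ "sex",
    ann$class %in% c("snp", "control") ~ "snp_control",
    ann$detection_fail == 1L ~ "detection",
    TRUE ~ "keep"
  )
  keep <- category == "keep"
  report <- tibble::tibble(
    input = nrow(beta),
    sex = sum(category == "sex"),
    snp_control = sum(category == "snp_control"),
    detection = sum(category == "detection"),
    removed = sum(!keep),
    retained = sum(keep)
  )
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' Tukey outlier fences at three interquartile ranges
#'
#' Lower/upper fence = Q1 - 3 IQR and Q3 + 3 IQR, with quartiles by linear
#' interpolation (the type-7 convention). Values *strictly* outside the
#' fences are outliers; the boundary itself is retained.
#'
#' @param values Numeric vector; at least 4 non-missing values required.
#' @param multiplier IQR multiplier (default 3).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' tukey_fences(c(0.1, 0.2, 0.3, 0.4, 1.0)) # (-0.4, 1.0)
#' @export
tukey_fences <- function(values, multiplier = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    abort("insufficient data: Tukey fences need >= 4 non-missing values.")
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - multiplier * iqr, upper = q[2] + multiplier * iqr)
}

#' Mask per-probe outlying beta values
#'
#' For each probe, values strictly outside the probe's [tukey_fences()] are
#' set to missing; downstream regressions are complete-case per probe, so a
#' masked cell drops that sample for that probe only. Probes with fewer than
#' 4 non-missing values are left untouched and flagged.
#'
#' @param beta Numeric beta matrix, probes x samples.
#' @param multiplier IQR multiplier passed to [tukey_fences()].
#' @return A list: `beta` (masked matrix) and `report` — tibble with
#'   `probe_id`, `n_outliers`, `flagged_insufficient`.
#' @export
remove_outliers <- function(beta, multiplier = 3) {
  assert_beta_matrix(beta)
  n_out <- integer(nrow(beta))
  flagged <- logical(nrow(beta))
  for (i in seq_len(nrow(beta))) {
    x <- beta[i, ]
    if (sum(!is.na(x)) < 4) {
      flagged[i] <- TRUE
      next
    }
    f <- tukey_fences(x, multiplier = multiplier)
    out <- !is.na(x) & (x < f[["lower"]] | x > f[["upper"]])
    if (any(out)) {
      beta[i, out] <- NA_real_
      n_out[i] <- sum(out)
    }
  }
  list(
    beta = beta,
    report = tibble::tibble(
      probe_id = rownames(beta),
      n_outliers = n_out,
      flagged_insufficient = flagged
    )
  )
}

#' Flag scan results against the cross-reactive/polymorphic probe list
#'
#' Probes on the published cross-reactive or polymorphic list are flagged,
#' never removed: hits stay in the results so a flagged signal can be judged
#' rather than silently discarded.
#'
#' @param results An EWAS results tibble containing `probe_id` (e.g. from
#'   [run_ewas()]).
#' @param annotation Annotation tibble with a `chen_flag` column.
#' @return `results` with a logical `chen_flag` column added/replaced.
#' @export
flag_chen <- function(results, annotation) {
  idx <- match(results$probe_id, annotation$probe_id)
  results$chen_flag <- !is.na(idx) & annotation$chen_flag[idx] == 1L
  results
}
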