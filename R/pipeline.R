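load_or <- function(x, loader, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      abort(sprintf("config error: %s path does not exist: %s", what, x))
    }
    loader(x)
  } else {
    x
  }
}

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory objects (as produced by [generate_dataset()]) or
#' file paths (as written by [write_dataset()]); paths are validated and
#' loaded here, so a bad path fails at configuration time with no partial
#' outputs. Every tunable default of the pipeline lives here.
#'
#' @param beta Beta matrix or TSV path.
#' @param annotation Annotation tibble or TSV path.
#' @param pheno Phenotype tibble or CSV path.
#' @param responses Optional long-format response table or CSV path; when
#'   supplied, case status is derived from it under `rules`, otherwise
#'   `pheno[[condition]]` is used directly.
#' @param catalog A [catalog_store()], or a TSV path/URL for one.
#' @param variable_map Tibble (`trait`, `variable`) or CSV path mapping
#'   harvested traits to cohort variable names.
#' @param condition Condition label; also the name given to the derived
#'   status column (default "condition").
#' @param threshold Suggestive hit threshold for the scan (default 1e-5).
#' @param n_permutations Permutations for surrogate-variable count
#'   estimation (default 20).
#' @param max_sv Upper cap on the number of surrogate variables (default 10).
#' @param eligibility_min Minimum per-cell count in the testing phase
#'   (default 5).
#' @param adjusters Adjustment columns for the adjusted models.
#' @param a_priori Variables always tested regardless of harvesting.
#' @param rules [case_rules()] for status derivation.
#' @param comorbidity_exclusions Sample ids excluded under the
#'   comorbidity-excluded sensitivity variant.
#' @param seed Integer seed for all pipeline randomness.
#' @param output_dir Optional directory for stage outputs; `NULL` keeps
#'   everything in memory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta, annotation, pheno, responses = NULL,
                            catalog, variable_map,
                            condition = "condition",
                            threshold = 1e-5,
                            n_permutations = 20,
                            max_sv = 10,
                            eligibility_min = 5,
                            adjusters = c("sep", "aam_months"),
                            a_priori = character(),
                            rules = case_rules(),
                            comorbidity_exclusions = character(),
                            seed = 1L,
                            output_dir = NULL) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  cfg <- list(
    beta = load_or(beta, read_beta_matrix, "beta matrix"),
    annotation = load_or(annotation, read_annotation, "annotation"),
    pheno = load_or(
      pheno, function(p) readr::read_csv(p, show_col_types = FALSE), "pheno"
    ),
    responses = if (!is.null(responses)) {
      load_or(responses,
              function(p) readr::read_csv(p, show_col_types = FALSE),
              "responses")
    },
    catalog = if (inherits(catalog, "catalog_store")) catalog else
      catalog_store(path = catalog),
    variable_map = load_or(
      variable_map, function(p) readr::read_csv(p, show_col_types = FALSE),
      "variable map"
    ),
    condition = condition,
    threshold = threshold,
    n_permutations = n_permutations,
    max_sv = max_sv,
    eligibility_min = eligibility_min,
    adjusters = adjusters,
    a_priori = a_priori,
    rules = rules,
    comorbidity_exclusions = comorbidity_exclusions,
    seed = assert_count(seed, "seed"),
    output_dir = output_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full hypothesis-generating and hypothesis-testing pipeline
#'
#' Executes, in order: case-status derivation, probe filtering, per-probe
#' outlier masking, surrogate-variable estimation (exposure protected),
#' the minimally adjusted methylation scan, hit selection and
#' cross-reactive-list flagging, catalog trait harvesting for hits and
#' their resident genes, and the logistic hypothesis-testing battery.
#' Identical seed and inputs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param battery_case_level Which status stratum is treated as the case
#'   group in the testing phase: `"case"` (default) or `"less_severe"`.
#' @return A `pipeline_result` list: `status`, `qc_report`,
#'   `outlier_report`, `n_sv`, `svs`, `ewas` (an `ewas_result`), `hits`,
#'   `hypotheses`, `associations`, and `report` (per-stage counts, lambda,
#'   seed).
#' @export
run_pipeline <- function(config, battery_case_level = "case") {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]

  # --- case definitions ------------------------------------------------------
  status <- if (!is.null(config$responses)) {
    derive_status(config$responses, config$rules)
  } else {
    tibble::tibble(
      sample_id = config$pheno$sample_id,
      status = factor(
        dplyr::case_when(
          config$pheno[[config$condition]] == 1 ~ "case",
          config$pheno[[config$condition]] == 0 ~ "control",
          TRUE ~ "excluded"
        ),
        levels = c("case", "less_severe", "control", "excluded")
      ),
      first_report_wave = NA_real_
    )
  }

  # --- methylation QC --------------------------------------------------------
  filt <- filter_probes(config$beta, config$annotation)
  masked <- remove_outliers(filt$beta)
  beta_qc <- masked$beta

  # --- surrogate variables (case/control samples only) -----------------------
  st_cc <- status[status$status %in% c("case", "control"), ]
  pheno_cc <- config$pheno[match(st_cc$sample_id, config$pheno$sample_id), ]
  pheno_cc$.case <- as.integer(st_cc$status == "case")
  keep <- intersect(colnames(beta_qc), pheno_cc$sample_id)
  pheno_cc <- pheno_cc[match(keep, pheno_cc$sample_id), ]
  beta_cc <- beta_qc[, keep, drop = FALSE]
  design <- build_design(pheno_cc, case = ".case", age = "age")
  n_sv <- estimate_n_sv(beta_cc, design,
                        n_permutations = config$n_permutations,
                        seed = sub_seed(config$seed, 1))
  n_sv <- min(n_sv, config$max_sv)
  svs <- if (n_sv >= 1) compute_svs(beta_cc, design, n_sv = n_sv)

  # --- the scan --------------------------------------------------------------
  ewas <- run_ewas(beta_cc, pheno_cc, svs = svs, case = ".case", age = "age",
                   threshold = config$threshold)
  ewas$results <- flag_chen(ewas$results, config$annotation)
  hits <- select_hits(ewas)

  # --- catalog harvest -------------------------------------------------------
  hypotheses <- harvest_traits(hits, config$annotation, config$catalog,
                               condition = config$condition)

  # --- hypothesis-testing battery -------------------------------------------
  pheno_battery <- config$pheno
  case_stat <- status$status[match(pheno_battery$sample_id, status$sample_id)]
  pheno_battery[[config$condition]] <- dplyr::case_when(
    as.character(case_stat) == battery_case_level ~ 1L,
    as.character(case_stat) == "control" ~ 0L,
    TRUE ~ NA_integer_
  )
  associations <- run_battery(
    pheno_battery, hypotheses, config$variable_map,
    conditions = config$condition, adjusters = config$adjusters,
    a_priori = config$a_priori, min_cell = config$eligibility_min
  )

  report <- list(
    seed = config$seed,
    n_samples_input = ncol(config$beta),
    n_case = sum(status$status == "case"),
    n_less_severe = sum(status$status == "less_severe"),
    n_control = sum(status$status == "control"),
    n_excluded = sum(status$status == "excluded"),
    probes_input = nrow(config$beta),
    probes_removed = filt$report$removed,
    probes_retained = filt$report$retained,
    outlier_cells_masked = sum(masked$report$n_outliers),
    n_sv = n_sv,
    lambda = ewas$lambda,
    n_hits = length(hits),
    n_traits = nrow(hypotheses),
    n_unmapped = length(attr(associations, "unmapped")),
    tests_run = sum(!associations$omitted),
    tests_omitted = sum(associations$omitted),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )

  result <- structure(
    list(status = status, qc_report = filt$report,
         outlier_report = masked$report, n_sv = n_sv, svs = svs,
         ewas = ewas, hits = hits, hypotheses = hypotheses,
         associations = associations, report = report),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(result, config)
  }
  result
}

write_pipeline_outputs <- function(result, config, subdir = NULL) {
  dir <- config$output_dir
  if (!is.null(subdir)) dir <- file.path(dir, subdir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$status, file.path(dir, "status.csv"))
  ann <- config$annotation
  res <- result$ewas$results |>
    dplyr::left_join(ann[, c("probe_id", "chr", "pos", "gene")],
                     by = "probe_id") |>
    dplyr::select("probe_id", "chr", "pos", "gene", "beta", "se",
                  "ci_low", "ci_high", "p", "n", "chen_flag")
  readr::write_tsv(res, file.path(dir, "ewas_results.tsv"))
  writeLines(result$hits, file.path(dir, "hits.txt"))
  readr::write_tsv(tibble::as_tibble(result$hypotheses),
                   file.path(dir, "traits.tsv"))
  readr::write_tsv(result$associations, file.path(dir, "associations.tsv"))
  p_ok <- result$ewas$results$p
  readr::write_tsv(qq_data(p_ok[!is.na(p_ok)]), file.path(dir, "qq.tsv"))
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Re-run the pipeline under a sensitivity variant
#'
#' * `"comorbidity_excluded"` — cases with listed comorbid sample ids are
#'   excluded and all stages re-run; with an empty exclusion list this is
#'   identical to the primary run.
#' * `"less_severe"` — the generating phase runs as primary, but the testing
#'   phase treats the symptom-without-doctor stratum as the case group
#'   (controls unchanged, primary cases dropped).
#' * `"pre_measurement_only"` — samples whose first symptom report postdates
#'   their methylation measurement age are excluded and all stages re-run.
#'
#' @param config A [pipeline_config()].
#' @param variant One of the three variant names.
#' @return A `pipeline_result` (outputs written under a variant-named
#'   subdirectory when the config has an output directory).
#' @export
run_sensitivity <- function(config,
                            variant = c("comorbidity_excluded", "less_severe",
                                        "pre_measurement_only")) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  config$output_dir <- NULL

  result <- switch(
    variant,
    comorbidity_excluded = {
      config$rules$comorbidity_exclusions <- unique(c(
        config$rules$comorbidity_exclusions, config$comorbidity_exclusions
      ))
      run_pipeline(config)
    },
    less_severe = run_pipeline(config, battery_case_level = "less_severe"),
    pre_measurement_only = {
      mw <- setNames(config$pheno$age, config$pheno$sample_id)
      config$rules$exclude_post_measurement <- TRUE
      config$rules$measurement_wave <- mw
      run_pipeline(config)
    }
  )
  if (!is.null(out_dir)) {
    config$output_dir <- out_dir
    write_pipeline_outputs(result, config, subdir = variant)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<pipeline_result> %d cases / %d controls (%d less-severe, ",
           "%d excluded)\n  probes %d -> %d retained; nSV = %d; ",
           "lambda = %s\n  hits = %d; traits harvested = %d; ",
           "tests run = %d (omitted %d)\n"),
    r$n_case, r$n_control, r$n_less_severe, r$n_excluded,
    r$probes_input, r$probes_retained, r$n_sv,
    ifelse(is.na(r$lambda), "NA", sprintf("%.3f", r$lambda)),
    r$n_hits, r$n_traits, r$tests_run, r$tests_omitted
  ))
  invisible(x)
}
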