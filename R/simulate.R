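#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles the knobs of the synthetic-data generator. The generator plants
#' three kinds of structure into an otherwise-null beta matrix:
#'
#' * **direct** probes — methylation shifted by case status itself;
#' * **confounded** probes — methylation shifted by a continuous confounder
#'   phenotype that *also* raises the odds of being a case (a common cause,
#'   the structure a minimally adjusted scan deliberately leverages);
#' * **batch** probes — methylation shifted by a technical batch label
#'   (the structure surrogate variable analysis should absorb).
#'
#' All remaining probes are null. Effects are on the beta-value scale
#' (methylation fraction units); values are clipped to \[0, 1\] after noise.
#'
#' @param n_samples,n_probes Cohort and array size.
#' @param n_direct_probes,n_confounded_probes,n_batch_probes Number of probes
#'   of each planted role; must sum to at most `n_probes`.
#' @param direct_effect Beta-scale shift at direct probes per unit case status.
#' @param confounder_effect_meth Beta-scale shift at confounded probes per unit
#'   of the (standard-normal) confounder.
#' @param confounder_effect_logodds Log-odds increment of case status per unit
#'   confounder.
#' @param batch_effect Beta-scale shift at batch probes for the second batch.
#' @param batch_case_assoc Association between batch assignment and case
#'   status: the probability of landing in the second batch is
#'   `0.5 + batch_case_assoc * (case - 0.5)`. The default 0 keeps batch
#'   independent of the exposure (batch only adds outcome variance, which
#'   *deflates* genomic inflation); positive values emulate the
#'   plate-assignment confounding that inflates test statistics and that
#'   surrogate-variable adjustment is meant to remove.
#' @param baseline_prevalence Case probability at confounder = 0.
#' @param noise_sd Standard deviation of the independent Gaussian measurement
#'   noise on the beta scale.
#' @param missing_rate Fraction of beta cells set missing at random.
#' @param less_severe_rate Fraction of controls whose questionnaire history
#'   reports the symptom without a doctor visit (exercises the less-severe
#'   stratum downstream).
#' @param confounder_trait Trait name the confounder represents (used when
#'   building a matching catalog fixture).
#' @param seed Single integer seed controlling all randomness.
#' @return A `sim_config` list.
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_samples = 500,
                       n_probes = 2000,
                       n_direct_probes = 5,
                       n_confounded_probes = 5,
                       n_batch_probes = 50,
                       direct_effect = 0.05,
                       confounder_effect_meth = 0.05,
                       confounder_effect_logodds = 1.0,
                       batch_effect = 0.05,
                       batch_case_assoc = 0,
                       baseline_prevalence = 0.15,
                       noise_sd = 0.02,
                       missing_rate = 0,
                       less_severe_rate = 0.05,
                       confounder_trait = "smoking",
                       seed = 1L) {
  cfg <- list(
    n_samples = assert_count(n_samples, "n_samples", min = 1),
    n_probes = assert_count(n_probes, "n_probes", min = 1),
    n_direct_probes = assert_count(n_direct_probes, "n_direct_probes"),
    n_confounded_probes = assert_count(n_confounded_probes, "n_confounded_probes"),
    n_batch_probes = assert_count(n_batch_probes, "n_batch_probes"),
    direct_effect = direct_effect,
    confounder_effect_meth = confounder_effect_meth,
    confounder_effect_logodds = confounder_effect_logodds,
    batch_effect = batch_effect,
    batch_case_assoc = batch_case_assoc,
    baseline_prevalence = baseline_prevalence,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    less_severe_rate = less_severe_rate,
    confounder_trait = confounder_trait,
    seed = assert_count(seed, "seed")
  )
  n_special <- cfg$n_direct_probes + cfg$n_confounded_probes + cfg$n_batch_probes
  if (n_special > cfg$n_probes) {
    abort("planted probe counts exceed `n_probes`: inconsistent configuration.")
  }
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1) {
    abort("`baseline_prevalence` must be in (0, 1).")
  }
  if (cfg$noise_sd < 0 || cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`noise_sd` must be >= 0 and `missing_rate` in [0, 1).")
  }
  if (abs(cfg$batch_case_assoc) > 1) {
    abort("`batch_case_assoc` must be in [-1, 1].")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic methylation cohort with planted structure
#'
#' Draws a standard-normal confounder per sample, assigns case status from a
#' logistic model of the confounder, and builds a probes-by-samples beta
#' matrix of `baseline + role-specific shift + Gaussian noise`, clipped to
#' \[0, 1\]. Also emits a long-format questionnaire-response history
#' consistent with the planted status (cases report the symptom and a doctor
#' visit; a configurable fraction of controls report the symptom only), a
#' probe annotation manifest, and a truth record naming each probe's role.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   `beta` (numeric matrix, probes x samples),
#'   `pheno` (tibble: sample_id, condition, age, batch, confounder, sep,
#'   aam_months), `responses` (tibble: sample_id, wave, symptom, doctor,
#'   severity), `annotation` (tibble manifest), and
#'   `truth` (list: `roles` named character vector over probes,
#'   `confounder_trait`, `confounder_variable`, `batch_variable`).
#' @examples
#' d <- generate_dataset(sim_config(n_samples = 40, n_probes = 50, seed = 3))
#' dim(d$beta)
#' table(d$truth$roles)
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_samples
  m <- config$n_probes

  withr::with_seed(config$seed, {
    sample_id <- sprintf("S%04d", seq_len(n))
    probe_id <- sprintf("cg%08d", seq_len(m))

    confounder <- rnorm(n)
    lin <- qlogis(config$baseline_prevalence) +
      config$confounder_effect_logodds * confounder
    condition <- rbinom(n, 1L, plogis(lin))
    age <- sample(c(15L, 17L), n, replace = TRUE, prob = c(0.3, 0.7))
    p_b2 <- 0.5 + config$batch_case_assoc * (condition - 0.5)
    batch <- ifelse(runif(n) < p_b2, "b2", "b1")
    sep <- rbinom(n, 1L, 0.3)
    aam_months <- rnorm(n, mean = 150, sd = 12)

    roles <- rep("null", m)
    idx <- seq_len(config$n_direct_probes + config$n_confounded_probes +
                     config$n_batch_probes)
    roles[idx] <- rep(
      c("direct", "confounded", "batch"),
      times = c(config$n_direct_probes, config$n_confounded_probes,
                config$n_batch_probes)
    )

    baseline <- runif(m, 0.2, 0.8)
    shift <- matrix(0, nrow = m, ncol = n)
    add_shift <- function(role, per_sample, effect) {
      k <- sum(roles == role)
      if (k > 0 && effect != 0) {
        shift[roles == role, ] <<- shift[roles == role, , drop = FALSE] +
          effect * matrix(per_sample, k, n, byrow = TRUE)
      }
    }
    add_shift("direct", condition, config$direct_effect)
    add_shift("confounded", confounder, config$confounder_effect_meth)
    add_shift("batch", as.numeric(batch == "b2"), config$batch_effect)

    beta <- baseline + shift +
      matrix(rnorm(m * n, sd = config$noise_sd), m, n)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(probe_id, sample_id)

    if (config$missing_rate > 0) {
      beta[runif(m * n) < config$missing_rate] <- NA_real_
    }

    # Questionnaire history at three waves; "ever" semantics downstream.
    less_severe <- condition == 0 & runif(n) < config$less_severe_rate
    responses <- tidyr::expand_grid(
      sample_id = sample_id,
      wave = c(13L, 15L, 17L)
    ) |>
      dplyr::left_join(
        tibble::tibble(sample_id, condition, less_severe),
        by = "sample_id"
      ) |>
      dplyr::mutate(
        symptom = dplyr::case_when(
          .data$wave == 15L & (.data$condition == 1L | .data$less_severe) ~ "yes",
          .data$wave == 17L & .data$condition == 1L ~ "yes",
          TRUE ~ "no"
        ),
        doctor = dplyr::if_else(
          .data$symptom == "yes" & .data$condition == 1L, "yes",
          dplyr::if_else(.data$symptom == "yes", "no", NA_character_)
        ),
        severity = NA_character_
      ) |>
      dplyr::select("sample_id", "wave", "symptom", "doctor", "severity")

    # Confounded probes sit in named genes so gene-level lookups are testable.
    gene <- rep("", m)
    gene[roles == "confounded"] <-
      sprintf("GENE%d", seq_len(sum(roles == "confounded")))
    annotation <- tibble::tibble(
      probe_id = probe_id,
      chr = as.character(1L + (seq_len(m) - 1L) %% 22L),
      pos = 1000L + 100L * seq_len(m),
      gene = gene,
      class = "cpg",
      detection_fail = 0L,
      chen_flag = 0L
    )

    pheno <- tibble::tibble(
      sample_id, condition = as.integer(condition), age,
      batch, confounder, sep, aam_months
    )

    list(
      beta = beta,
      pheno = pheno,
      responses = responses,
      annotation = annotation,
      truth = list(
        roles = setNames(roles, probe_id),
        confounder_trait = config$confounder_trait,
        confounder_variable = "confounder",
        batch_variable = "batch"
      )
    )
  })
}

#' Build a catalog store matching a simulated dataset's planted truth
#'
#' Confounded probes (and their annotated genes) receive a catalog entry for
#' the planted confounder's trait; null, direct and batch probes carry no
#' entries. Querying the resulting store with the planted hits must therefore
#' recover the confounder trait, making the end-to-end harvest testable
#' offline.
#'
#' @param truth Truth record from [generate_dataset()].
#' @param annotation Probe annotation from the same dataset.
#' @return A [catalog_store()] backed by the constructed records.
#' @export
generate_catalog_fixture <- function(truth, annotation) {
  if (!all(names(truth$roles) %in% annotation$probe_id)) {
    abort("truth refers to probes absent from the annotation.")
  }
  confounded <- names(truth$roles)[truth$roles == "confounded"]
  ann <- annotation[match(confounded, annotation$probe_id), ]
  records <- tibble::tibble(
    cpg = confounded,
    gene = ann$gene,
    trait = rep(truth$confounder_trait, length(confounded)),
    study_id = rep("SIM0001", length(confounded)),
    p = rep(1e-8, length(confounded))
  )
  catalog_store(records = records)
}

#' Write a simulated dataset to plain-text files
#'
#' Beta matrix as TSV (first column `probe_id`, one column per sample),
#' phenotype and response tables as CSV, annotation as TSV, truth as JSON.
#'
#' @param data List from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  beta_tbl <- tibble::as_tibble(data$beta, rownames = "probe_id")
  readr::write_tsv(beta_tbl, file.path(dir, "beta.tsv"))
  readr::write_csv(data$pheno, file.path(dir, "pheno.csv"))
  readr::write_csv(data$responses, file.path(dir, "responses.csv"))
  readr::write_tsv(data$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(
    list(
      roles = as.list(data$truth$roles),
      confounder_trait = data$truth$confounder_trait,
      confounder_variable = data$truth$confounder_variable,
      batch_variable = data$truth$batch_variable
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read a beta matrix written by [write_dataset()]
#'
#' @param path TSV with first column `probe_id` and one numeric column per
#'   sample.
#' @return Numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl[[1]]
  assert_beta_matrix(mat)
  mat
}
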