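#' Rules for deriving case status from questionnaire histories
#'
#' The defaults reproduce the primary analysis: a case is anyone who ever
#' reported the symptom *and* a doctor visit for it; reporting the symptom
#' without ever visiting a doctor is the less-severe stratum; never reporting
#' the symptom (or reporting only "mild" severity at the age-15 wave, when
#' that flag is on) is a control. Sensitivity variants are re-runs with
#' different rules, not different code.
#'
#' @param require_doctor If `TRUE` (default) a doctor visit is required for
#'   case status; if `FALSE` any symptom report qualifies.
#' @param mild_age15_as_control Treat a history whose only report is severity
#'   "mild" at the age-15 wave as a control (default `TRUE`).
#' @param comorbidity_exclusions Character vector of sample ids to exclude
#'   (e.g. thyroid problems, PCOS, endometriosis).
#' @param exclude_post_measurement If `TRUE`, samples whose first symptom
#'   report postdates their methylation measurement are excluded;
#'   `measurement_wave` must then be supplied.
#' @param measurement_wave Named numeric vector: methylation-measurement wave
#'   per sample id.
#' @return A `case_rules` list.
#' @export
case_rules <- function(require_doctor = TRUE,
                       mild_age15_as_control = TRUE,
                       comorbidity_exclusions = character(),
                       exclude_post_measurement = FALSE,
                       measurement_wave = NULL) {
  if (exclude_post_measurement && is.null(measurement_wave)) {
    abort("`measurement_wave` is required when `exclude_post_measurement` is on.")
  }
  structure(
    list(
      require_doctor = isTRUE(require_doctor),
      mild_age15_as_control = isTRUE(mild_age15_as_control),
      comorbidity_exclusions = as.character(comorbidity_exclusions),
      exclude_post_measurement = isTRUE(exclude_post_measurement),
      measurement_wave = measurement_wave
    ),
    class = "case_rules"
  )
}

#' Derive case/control/less-severe status from repeated symptom reports
#'
#' Applies "ever" semantics over waves: any wave with symptom = yes and
#' doctor = yes makes a case (under the default rules); symptom = yes at some
#' wave but never a doctor visit makes the less-severe stratum; never
#' reporting the symptom makes a control. A missing doctor answer after a
#' symptom report counts as no doctor visit for that wave. Samples with no
#' non-missing symptom answer at any wave, samples on the comorbidity
#' exclusion list, and (when flagged) samples whose first report postdates
#' their methylation measurement are excluded.
#'
#' @param responses Long-format tibble/data frame with columns `sample_id`,
#'   `wave` (numeric, e.g. age in years), `symptom` ("yes"/"no"/`NA`),
#'   `doctor` ("yes"/"no"/`NA`), and optionally `severity`.
#' @param rules A [case_rules()] object.
#' @return A tibble with one row per sample: `sample_id`,
#'   `status` (factor: case, less_severe, control, excluded) and
#'   `first_report_wave` (`NA` unless the symptom was ever reported).
#' @examples
#' resp <- tibble::tibble(
#'   sample_id = c("a", "a", "b", "c"),
#'   wave = c(13, 15, 13, 15),
#'   symptom = c("no", "yes", "no", "yes"),
#'   doctor = c(NA, "yes", NA, "no"),
#'   severity = NA_character_
#' )
#' derive_status(resp)
#' @export
derive_status <- function(responses, rules = case_rules()) {
  responses <- tibble::as_tibble(responses)
  needed <- c("sample_id", "wave", "symptom", "doctor")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols)) {
    abort(paste0("responses lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"severity" %in% names(responses)) responses$severity <- NA_character_

  bad <- !is.na(responses$doctor) & responses$doctor == "yes" &
    (is.na(responses$symptom) | responses$symptom != "yes")
  if (any(bad)) {
    abort(sprintf(
      "data integrity: doctor = yes without symptom = yes for sample(s) %s",
      paste(unique(responses$sample_id[bad]), collapse = ", ")
    ))
  }

  per_sample <- responses |>
    dplyr::mutate(
      symptom_yes = !is.na(.data$symptom) & .data$symptom == "yes",
      doctor_yes = .data$symptom_yes &
        !is.na(.data$doctor) & .data$doctor == "yes",
      # A mild-only report at the age-15 wave can be discounted by rule.
      mild15 = .data$symptom_yes & .data$wave == 15 &
        !is.na(.data$severity) & .data$severity == "mild"
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      any_answer = any(!is.na(.data$symptom)),
      ever_symptom = any(.data$symptom_yes),
      ever_doctor = any(.data$doctor_yes),
      only_mild15 = all(!.data$symptom_yes | .data$mild15) &
        any(.data$symptom_yes),
      first_report_wave = ifelse(
        any(.data$symptom_yes), min(.data$wave[.data$symptom_yes]), NA_real_
      ),
      .groups = "drop"
    )

  qualifies <- if (rules$require_doctor) {
    per_sample$ever_doctor
  } else {
    per_sample$ever_symptom
  }
  mild_ctrl <- rules$mild_age15_as_control & per_sample$only_mild15 &
    !per_sample$ever_doctor

  status <- dplyr::case_when(
    !per_sample$any_answer ~ "excluded",
    per_sample$sample_id %in% rules$comorbidity_exclusions ~ "excluded",
    mild_ctrl ~ "control",
    qualifies ~ "case",
    per_sample$ever_symptom ~ "less_severe",
    TRUE ~ "control"
  )

  if (rules$exclude_post_measurement) {
    mw <- rules$measurement_wave[per_sample$sample_id]
    late <- !is.na(per_sample$first_report_wave) & !is.na(mw) &
      per_sample$first_report_wave > mw
    status[late & status %in% c("case", "less_severe")] <- "excluded"
  }

  tibble::tibble(
    sample_id = per_sample$sample_id,
    status = factor(status,
                    levels = c("case", "less_severe", "control", "excluded")),
    first_report_wave = per_sample$first_report_wave
  )
}
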