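# Published cohort summary encoded as per-group cell counts. Group order
# everywhere: dysmenorrhea cases (641), dysmenorrhea controls (1254),
# HMB cases (527), HMB controls (2083). Binary rows store positive counts,
# continuous rows store mean/SD; every row stores per-group missing counts.
table1_cells <- function() {
  bin <- tibble::tribble(
    ~variable,             ~pos,                  ~miss,
    "mat_uni_degree",      c(70, 208, 46, 361),   c(72, 137, 65, 188),
    "g0_alcohol_preg",     c(394, 785, 317, 1336), c(151, 258, 129, 397),
    "g0_smoking_preg",     c(142, 222, 132, 364), c(95, 184, 86, 282),
    "g0_hdp",              c(113, 201, 97, 310),  c(44, 67, 41, 104),
    "g0_preeclampsia",     c(9, 26, 11, 42),      c(44, 67, 41, 104),
    "alcohol_13",          c(165, 242, 137, 430), c(311, 649, 240, 1013),
    "smoked_13",           c(99, 92, 91, 160),    c(160, 383, 130, 544),
    "oral_contraception",  c(445, 271, 390, 511), c(2, 7, 2, 11),
    "comorbidity",         c(39, 30, 36, 58),     c(363, 837, 301, 1292)
  )
  cont <- tibble::tribble(
    ~variable,        ~mean,                        ~sd,                      ~miss,
    "g0_bmi_preg",    c(23.1, 22.9, 23.1, 22.8),    c(3.9, 3.9, 4.0, 3.7),    c(94, 201, 80, 301),
    "gestational_age", c(39.6, 39.4, 39.5, 39.6),   c(1.7, 1.8, 1.8, 1.8),    c(39, 64, 35, 100),
    "bmi_7",          c(16.8, 16.3, 16.8, 16.3),    c(2.6, 2.1, 2.5, 2.1),    c(137, 318, 114, 450),
    "cholesterol_7",  c(4.5, 4.5, 4.5, 4.5),        c(0.7, 0.7, 0.7, 0.7),    c(309, 636, 253, 1008),
    "cotinine_7",     c(1.5, 1.2, 1.5, 1.2),        c(1.4, 1.2, 1.5, 1.1),    c(302, 617, 254, 978),
    "nonword_rep_8",  c(7.2, 7.3, 7.1, 7.4),        c(2.5, 2.6, 2.4, 2.5),    c(62, 368, 145, 527),
    "crp_9",          c(1.2, 0.7, 1.2, 0.8),        c(3.7, 1.4, 3.2, 2.7),    c(322, 625, 279, 981),
    "aam_months",     c(146.0, 151.5, 146.4, 150.4), c(12.8, 12.6, 13.3, 12.3), c(123, 331, 91, 478),
    "ace_16",         c(2.0, 1.6, 2.1, 1.5),        c(1.5, 1.7, 1.9, 1.5),    c(419, 892, 362, 1433)
  )
  list(binary = bin, continuous = cont,
       group_sizes = c(dys_case = 641L, dys_ctrl = 1254L,
                       hmb_case = 527L, hmb_ctrl = 2083L))
}

#' Variable declarations for the cohort summary fixture
#'
#' One row per candidate phenotype: declared type, measurement epoch, and
#' whether the variable was an a-priori (previously reported) association
#' rather than a catalog-harvested one.
#'
#' @return A tibble with columns `variable`, `type`, `epoch`, `a_priori`.
#' @export
table1_variables <- function() {
  tibble::tribble(
    ~variable,            ~type,        ~epoch,      ~a_priori,
    "mat_uni_degree",     "binary",     "prenatal",  TRUE,
    "g0_alcohol_preg",    "binary",     "prenatal",  FALSE,
    "g0_smoking_preg",    "binary",     "prenatal",  FALSE,
    "g0_hdp",             "binary",     "prenatal",  FALSE,
    "g0_preeclampsia",    "binary",     "prenatal",  FALSE,
    "alcohol_13",         "binary",     "childhood", FALSE,
    "smoked_13",          "binary",     "childhood", TRUE,
    "oral_contraception", "binary",     "puberty",   TRUE,
    "comorbidity",        "binary",     "puberty",   TRUE,
    "g0_bmi_preg",        "continuous", "prenatal",  FALSE,
    "gestational_age",    "continuous", "prenatal",  FALSE,
    "bmi_7",              "continuous", "childhood", FALSE,
    "cholesterol_7",      "continuous", "childhood", FALSE,
    "cotinine_7",         "continuous", "childhood", FALSE,
    "nonword_rep_8",      "continuous", "childhood", FALSE,
    "crp_9",              "continuous", "childhood", FALSE,
    "aam_months",         "continuous", "puberty",   TRUE,
    "ace_16",             "continuous", "puberty",   FALSE
  )
}

# Deterministic vector with exact sample mean/SD: a standardised ramp.
exact_normalish <- function(n, mean, sd) {
  if (n < 2) return(rep(mean, n))
  z <- as.numeric(scale(seq_len(n)))
  mean + sd * z
}

#' Sample-level fixture reproducing a published cohort summary table
#'
#' Expands the per-group cell counts of the published dysmenorrhea/HMB
#' cohort characteristics table into an individual-level phenotype table:
#' 641 dysmenorrhea cases and 1,254 controls, 527 HMB cases and 2,083
#' controls, with every binary positive count, continuous mean/SD and
#' per-variable missing count reproduced exactly. The table does not publish
#' the overlap between the two condition subsamples, so the fixture keeps
#' them disjoint (a sample classified for one condition has missing status
#' for the other). Continuous values are deterministic standardised ramps
#' with the printed mean and SD; the fixture is for summary-level
#' reproduction, not individual-level realism.
#'
#' @return A tibble with `sample_id`, condition columns `dysmenorrhea` and
#'   `hmb` (1 = case, 0 = control, `NA` = not in that condition's sample),
#'   and one column per variable in [table1_variables()].
#' @examples
#' tab1 <- table1_fixture()
#' table(tab1$dysmenorrhea, useNA = "ifany")
#' @export
table1_fixture <- function() {
  cells <- table1_cells()
  sizes <- cells$group_sizes
  n_total <- sum(sizes)
  group <- rep(names(sizes), times = sizes)

  out <- tibble::tibble(
    sample_id = sprintf("P%04d", seq_len(n_total)),
    dysmenorrhea = dplyr::case_when(
      group == "dys_case" ~ 1L, group == "dys_ctrl" ~ 0L, TRUE ~ NA_integer_
    ),
    hmb = dplyr::case_when(
      group == "hmb_case" ~ 1L, group == "hmb_ctrl" ~ 0L, TRUE ~ NA_integer_
    )
  )

  fill_groups <- function(maker) {
    unlist(lapply(seq_along(sizes), function(g) maker(g, sizes[[g]])),
           use.names = FALSE)
  }

  for (i in seq_len(nrow(cells$binary))) {
    row <- cells$binary[i, ]
    out[[row$variable]] <- fill_groups(function(g, n) {
      pos <- row$pos[[1]][g]
      miss <- row$miss[[1]][g]
      c(rep(1L, pos), rep(NA_integer_, miss), rep(0L, n - pos - miss))
    })
  }
  for (i in seq_len(nrow(cells$continuous))) {
    row <- cells$continuous[i, ]
    out[[row$variable]] <- fill_groups(function(g, n) {
      miss <- row$miss[[1]][g]
      c(rep(NA_real_, miss),
        exact_normalish(n - miss, row$mean[[1]][g], row$sd[[1]][g]))
    })
  }
  out
}
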