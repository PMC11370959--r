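#' Open an EWAS-catalog store
#'
#' A store is a table of published CpG-phenotype associations with columns
#' `cpg`, `gene`, `trait`, `study_id`, `p`. It can come from an offline TSV
#' dump, a URL serving the same TSV (fetched once, then queried locally —
#' both backends are record-identical by construction), or an in-memory
#' records tibble.
#'
#' @param path Path to a TSV dump, or an `http(s)://` URL of one.
#' @param records In-memory tibble of records (overrides `path`).
#' @param version Optional version label carried in the store.
#' @return A `catalog_store` object.
#' @export
catalog_store <- function(path = NULL, records = NULL, version = NULL) {
  if (is.null(records)) {
    if (is.null(path)) abort("supply `path` (file or URL) or `records`.")
    if (grepl("^https?://", path)) {
      tmp <- tempfile(fileext = ".tsv")
      ok <- tryCatch(
        utils::download.file(path, tmp, quiet = TRUE, mode = "wb") == 0,
        error = function(e) FALSE, warning = function(w) FALSE
      )
      if (!ok) {
        abort(sprintf("catalog backend unreachable: %s (retryable)", path),
              class = "catalog_io_error")
      }
      path <- tmp
    } else if (!file.exists(path)) {
      abort(sprintf("catalog store not found: %s", path))
    }
    records <- readr::read_tsv(
      path,
      col_types = readr::cols(
        cpg = readr::col_character(), gene = readr::col_character(),
        trait = readr::col_character(), study_id = readr::col_character(),
        p = readr::col_double()
      )
    )
  }
  records <- tibble::as_tibble(records)
  needed <- c("cpg", "gene", "trait", "study_id", "p")
  if (!all(needed %in% names(records))) {
    abort(paste0("catalog records need columns: ",
                 paste(needed, collapse = ", ")))
  }
  records$gene[is.na(records$gene)] <- ""
  records$trait_norm <- normalize_trait(records$trait)
  records$gene_norm <- tolower(records$gene)
  structure(list(records = records, version = version %||% "unversioned"),
            class = "catalog_store")
}

#' Query a catalog store by CpG id
#'
#' @param store A [catalog_store()].
#' @param cpg A probe id; matched exactly.
#' @return Tibble of matching records (possibly empty).
#' @export
query_cpg <- function(store, cpg) {
  stopifnot(inherits(store, "catalog_store"))
  store$records[store$records$cpg == cpg, ]
}

#' Query a catalog store by gene symbol (case-insensitive)
#'
#' @param store A [catalog_store()].
#' @param gene A gene symbol.
#' @return Tibble of matching records (possibly empty).
#' @export
query_gene <- function(store, gene) {
  stopifnot(inherits(store, "catalog_store"))
  store$records[store$records$gene_norm == tolower(gene), ]
}

#' Harvest candidate phenotypes for hit CpGs and their resident genes
#'
#' For every hit probe, collects catalog traits reported for the CpG itself
#' (CpG-level provenance) and for any gene the manifest annotates the probe
#' to (gene-level provenance; probes with several symbols query each).
#' Traits are deduplicated case-insensitively after whitespace normalisation;
#' a trait found at both levels keeps CpG-level provenance. The output is
#' invariant to hit ordering and duplicate hit ids.
#'
#' @param hits Character vector of hit probe ids.
#' @param annotation Manifest tibble annotating every hit (`probe_id`,
#'   `gene` with semicolon-separated symbols).
#' @param store A [catalog_store()].
#' @param condition Optional condition label carried on the result.
#' @return A `hypothesis_set`: tibble with `trait` (first-seen spelling),
#'   `trait_norm`, `provenance` ("cpg-level"/"gene-level"), `sources`
#'   (collapsed CpG ids / gene symbols the trait traces to), `n_studies`.
#' @export
harvest_traits <- function(hits, annotation, store, condition = NULL) {
  stopifnot(inherits(store, "catalog_store"))
  hits <- sort(unique(hits))
  unknown <- setdiff(hits, annotation$probe_id)
  if (length(unknown)) {
    abort(paste0("hits missing from annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  empty <- tibble::tibble(
    trait = character(), trait_norm = character(), provenance = character(),
    sources = character(), n_studies = integer()
  )
  if (!length(hits)) {
    return(structure(empty, class = c("hypothesis_set", class(empty)),
                     condition = condition))
  }

  cpg_recs <- purrr::map_dfr(hits, function(h) {
    r <- query_cpg(store, h)
    if (nrow(r)) dplyr::mutate(r, source = h) else NULL
  })
  genes <- annotation$gene[match(hits, annotation$probe_id)]
  gene_syms <- sort(unique(unlist(strsplit(genes[genes != ""], ";", fixed = TRUE))))
  gene_recs <- purrr::map_dfr(gene_syms, function(g) {
    r <- query_gene(store, g)
    if (nrow(r)) dplyr::mutate(r, source = g) else NULL
  })

  level_tbl <- function(recs, level) {
    if (is.null(recs) || !nrow(recs)) return(NULL)
    recs |>
      dplyr::group_by(.data$trait_norm) |>
      dplyr::summarise(
        trait = dplyr::first(.data$trait),
        sources = paste(sort(unique(.data$source)), collapse = ";"),
        n_studies = dplyr::n_distinct(.data$study_id),
        .groups = "drop"
      ) |>
      dplyr::mutate(provenance = level)
  }
  combined <- dplyr::bind_rows(
    level_tbl(cpg_recs, "cpg-level"),
    level_tbl(gene_recs, "gene-level")
  )
  if (is.null(combined) || !nrow(combined)) {
    return(structure(empty, class = c("hypothesis_set", class(empty)),
                     condition = condition))
  }
  # CpG-level provenance wins when a trait is found at both levels
  out <- combined |>
    dplyr::arrange(.data$provenance, .data$trait_norm) |>
    dplyr::distinct(.data$trait_norm, .keep_all = TRUE) |>
    dplyr::select("trait", "trait_norm", "provenance", "sources", "n_studies") |>
    dplyr::arrange(.data$provenance, .data$trait_norm)
  structure(out, class = c("hypothesis_set", class(out)), condition = condition)
}

#' Fisher's exact enrichment of one trait among hit probes
#'
#' Builds the 2x2 table of (hit vs non-hit) x (trait-annotated vs not) over
#' the analysed probe universe and returns the two-sided exact p (Fisher's
#' test, hypergeometric summation) with the cross-product odds ratio (0.5
#' continuity added only when a cell is zero, for display).
#'
#' @param trait Trait name (matched after normalisation).
#' @param hits Character vector of hit probe ids (non-empty).
#' @param store A [catalog_store()].
#' @param universe Character vector of all analysed probe ids; `hits` must be
#'   a subset.
#' @return One-row tibble: `trait`, `odds_ratio`, `p`, and the four cells
#'   `hit_trait`, `hit_other`, `rest_trait`, `rest_other`.
#' @export
enrichment <- function(trait, hits, store, universe) {
  stopifnot(inherits(store, "catalog_store"))
  hits <- unique(hits)
  universe <- unique(universe)
  if (!length(hits)) abort("no hits: enrichment test impossible.")
  if (!all(hits %in% universe)) abort("`hits` must be a subset of `universe`.")
  tn <- normalize_trait(trait)
  if (!tn %in% store$records$trait_norm) {
    abort(sprintf("trait '%s' absent from the catalog store.", trait))
  }
  trait_probes <- unique(store$records$cpg[store$records$trait_norm == tn])
  in_trait <- universe %in% trait_probes
  in_hit <- universe %in% hits
  a <- sum(in_hit & in_trait)
  b <- sum(in_hit & !in_trait)
  cc <- sum(!in_hit & in_trait)
  d <- sum(!in_hit & !in_trait)
  p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
  or <- if (min(a, b, cc, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  tibble::tibble(
    trait = trait, odds_ratio = or, p = p,
    hit_trait = a, hit_other = b, rest_trait = cc, rest_other = d
  )
}

#' Load the bundled catalog fixture encoding published hit-trait tables
#'
#' The fixture reproduces, as catalog records, the CpG-level and gene-level
#' trait lists printed for the seven dysmenorrhea hit CpGs and the two HMB
#' hit CpGs. Record-level study ids are synthetic placeholders; the trait
#' lists are the published content.
#'
#' @return A [catalog_store()].
#' @export
published_catalog_fixture <- function() {
  catalog_store(
    path = system.file("extdata", "published_hits_catalog.tsv",
                       package = "ewasharvest"),
    version = "published-tables-fixture"
  )
}

#' Load the bundled annotation for the published hit CpGs
#'
#' @return Annotation tibble for the nine published hit probes (array
#'   manifest coordinates as printed).
#' @export
published_hits_annotation <- function() {
  read_annotation(system.file("extdata", "published_hits_annotation.tsv",
                              package = "ewasharvest"))
}

#' Load the published hit CpG effect-estimate fixture
#'
#' The printed per-probe effect estimates (beta, 95% CI, p) for the seven
#' dysmenorrhea and two HMB hit CpGs, as fixtures for formatting and
#' flagging checks. These are cohort-specific printed values, not anything
#' the package recomputes.
#'
#' @return Tibble with `condition`, `probe_id`, `beta`, `ci_low`, `ci_high`,
#'   `p`, `chr`, `pos`, `gene`.
#' @export
published_hits_results <- function() {
  readr::read_tsv(
    system.file("extdata", "published_hits_results.tsv",
                package = "ewasharvest"),
    col_types = readr::cols(
      condition = readr::col_character(),
      probe_id = readr::col_character(),
      beta = readr::col_double(), ci_low = readr::col_double(),
      ci_high = readr::col_double(), p = readr::col_double(),
      chr = readr::col_character(), pos = readr::col_integer(),
      gene = readr::col_character()
    )
  )
}
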