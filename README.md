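# ewasharvest

Hypothesis generation from DNA methylation data, for epidemiologists working
on under-researched conditions where there is little prior literature to say
which risk factors are worth testing. The package implements a three-stage
approach:

1. **Hypothesis-generating scan.** A *minimally adjusted* epigenome-wide
   association study (EWAS) of a binary condition: for each CpG probe `j`,

   `beta_j = b0 + b1 * case + b2 * age + g' * SV + e`

   — ordinary least squares with methylation (beta-value, the fraction of
   methylated cells, in [0, 1]) as the **outcome** and case status as the
   **exposure**, adjusted only for age at measurement and surrogate
   variables capturing technical batch structure. No adjustment for cell
   composition or lifestyle covariates, on purpose: CpGs associated with
   case status *through confounding* are exactly what the next stage
   harvests. Suggestive hits are CpGs with p < 1e-5 (strict).

2. **Catalog harvest.** Hit CpGs — and the genes they reside in — are looked
   up in an EWAS-catalog store of published CpG-phenotype associations; the
   deduplicated union of reported traits becomes the set of candidate
   phenotypes for the condition.

3. **Hypothesis-testing battery.** Each candidate phenotype available in the
   cohort is tested against the condition by logistic regression, unadjusted
   and adjusted for socioeconomic position and age at menarche, with
   continuous exposures z-scored and a "fewer than five participants per
   cell" omission rule.

Probe-level QC (sex-chromosome / SNP / control / detection-failure removal,
per-probe Tukey-fence outlier masking at Q1/Q3 +/- 3 IQR, cross-reactive-list
flagging), in-package iteratively reweighted surrogate variable analysis
with a permutation estimate of the SV count, genomic-inflation (lambda) and
QQ diagnostics, and case/control/less-severe status derivation from repeated
questionnaire waves are all included, as is a synthetic-data generator that
plants the confounding structure the method leverages so the whole pipeline
is testable without access-controlled cohort data.

## Worked example

```r
library(ewasharvest)

# a synthetic cohort with a planted confounder ("smoking"): the confounder
# shifts methylation at 5 CpGs AND raises the odds of being a case
d <- generate_dataset(sim_config(n_samples = 500, n_probes = 2000,
                                 n_confounded_probes = 5, seed = 1))
status <- derive_status(d$responses)

qc <- filter_probes(d$beta, d$annotation)
masked <- remove_outliers(qc$beta)

scan <- run_ewas(masked$beta, d$pheno, status = status)
glance(scan)
#> # A tibble: 1 x 7
#>   n_probes n_samples covariates  n_sv lambda threshold n_hits
#> 1     2000       470 case+age       0  0.930   0.00001     10

hits <- select_hits(scan)
store <- generate_catalog_fixture(d$truth, d$annotation)
harvest_traits(hits, d$annotation, store)
#> # A tibble: 1 x 5
#>   trait   trait_norm provenance sources                      n_studies
#> 1 smoking smoking    cpg-level  cg00000006;cg00000007;cg...          1

# the harvested trait, tested back against the condition in the cohort
logistic_test(d$pheno, "confounder", "condition")
#> # A tibble: 1 x 10
#>   exposure   condition model      odds_ratio ci_low ci_high        p     n
#> 1 confounder condition unadjusted       2.76   2.10    3.62 3.70e-13   500
```

The scan finds the confounder-linked CpGs among its hits even though no
direct causal path runs from case status to those CpGs; the catalog look-up
turns them into the trait name "smoking"; and the battery confirms the
planted positive association (odds ratio above 1 per SD of the confounder).
`run_pipeline()` chains all stages from one `pipeline_config()`, and
`run_sensitivity()` re-runs it under comorbidity-exclusion, less-severe-case
and pre-measurement-only variants.

A published-results fixture is bundled: `table1_fixture()` reproduces a
cohort characteristics table cell-for-cell (e.g. oral contraception use in
641 dysmenorrhea cases: `445 (69.4)`), and `published_catalog_fixture()`
encodes the trait lists of the nine published hit CpGs, from which
`harvest_traits()` recovers the printed tallies (9 CpG-level + 22 gene-level
traits for dysmenorrhea; 10 for heavy menstrual bleeding).

## What this package does not do

Raw IDAT preprocessing/normalisation and cell-count estimation are upstream
concerns (the scan consumes a ready beta matrix); region-level (DMR)
analysis, causal inference and multiple imputation are out of scope. The
method generates hypotheses — its output is a list of phenotype-condition
associations to carry into causally motivated analyses, not causal claims.
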