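---
title: "Leveraging confounding: the methods behind ewasharvest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leveraging confounding: the methods behind ewasharvest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasharvest)
```

## The idea

Most epigenome-wide association studies treat confounding as a nuisance and
adjust it away. This package inverts that logic for hypothesis generation:
a *minimally adjusted* scan of case status against methylation will pick up
CpGs whose association is driven by a common cause — an unmeasured
phenotype that both shifts methylation and changes the odds of the
condition. Published catalogs of CpG-phenotype associations then let us name
that common cause: if a hit CpG (or its resident gene) is known to respond
to smoking, "smoking" becomes a candidate risk factor for the condition,
testable directly in cohort data. Stage one generates hypotheses, stage two
names them, stage three tests them; nothing here is causal inference, and
the output is a short list of phenotype-condition associations worth
carrying into causally motivated designs.

## The scan model and its assumptions

For each probe $j$ the model is ordinary least squares on the beta-value
scale,

$$\beta_{ij} = b_{0j} + b_{1j}\,\mathrm{case}_i + b_{2j}\,\mathrm{age}_i +
  \gamma_j' \mathrm{SV}_i + \varepsilon_{ij},$$

with methylation as the outcome and case status as the exposure. The
direction is deliberate — the aim is not to estimate a causal effect of
methylation but to rank probes by association — and the covariate set is
deliberately minimal: age at measurement (samples are drawn at two ages) and
surrogate variables for technical batch. Cell composition is *not* adjusted:
cell-type shifts are themselves candidate hypotheses (immune involvement,
for instance) and adjusting them away would defeat the purpose. Analysis is
on beta-values rather than M-values because effect sizes are reported in
methylation-fraction units; p-values are two-sided t tests with
$n - k$ degrees of freedom, confidence intervals are Wald. Inference is
complete-case per probe, so an outlier masked at one probe drops that sample
for that probe only.

Suggestive hits are probes with $p < 10^{-5}$, strictly below — a
conventional suggestive threshold, not a genome-wide correction; the method
intentionally trades specificity for recall because stage three filters the
candidates anyway.

## Quality control

Probe filters run in a fixed order (sex chromosomes, then SNP/control
probes, then high-detection-p probes) so category tallies are deterministic
when a probe matches several. Detection failure is consumed as a manifest
flag, not recomputed, since no intensity data is in scope. Per-probe outlier
masking uses Tukey fences at $Q_1 - 3\,\mathrm{IQR}$ and
$Q_3 + 3\,\mathrm{IQR}$ with type-7 (linear interpolation) quartiles — the
most common quantile convention, fixed for reproducibility; values exactly
on a fence are kept ("outside" is strict), constant probes keep everything,
and probes with fewer than four observations are flagged rather than
masked. Probes on the published cross-reactive/polymorphic list are flagged
in results but never removed, so a suspect hit is visible rather than
silently gone.

## Surrogate variables

The number of surrogate variables is estimated by parallel analysis: the
matrix is residualised on the protected design (intercept, case, age), the
variance proportion of each singular component is compared with its null
distribution under independent within-probe permutation, and the leading run
of components above the null's 95th percentile is kept (20 permutations by
default; the run-based stopping rule is the conservative variant of the
standard criterion).

The surrogate variables themselves come from a two-step iteratively
reweighted decomposition. The initial estimate is the leading
right-singular vectors of the *residual* matrix — structurally orthogonal
to the protected design, so the exposure cannot seed the surrogate
variables. Each subsequent iteration (5 by default) weights probes by
evidence of association with the current surrogate variables and, from the
second iteration on, by evidence of *no* residual association with the
protected covariates given the surrogate variables, then recomputes the
decomposition of the weighted row-centred *raw* matrix. Two numerical
choices matter and were validated on simulations with a planted batch
factor:

* the final decomposition must use the raw (centred) matrix, not the
  residuals — a technical factor partially collinear with the exposure (the
  plate-assignment confounding that actually inflates test statistics) can
  then still be absorbed, and genomic inflation returns to ~1; a
  residual-space decomposition can only remove the exposure-orthogonal part
  and *raises* inflation after adjustment;
* the exposure-protection weight factor must not be applied against the
  first, residual-space anchor — there it zeroes out every probe of such a
  collinear factor and the decomposition collapses to noise.

The weights use the probability scale directly ($w = (1-p_{SV})\cdot
p_{protected}$) rather than an empirical-Bayes local-FDR posterior; the two
are monotone-equivalent for ranking probes and the simpler form has no
density-estimation failure modes on small simulated matrices. For probes
$\gg$ samples, right-singular vectors are computed from the
$n \times n$ Gram matrix, which is exact for the leading components and far
cheaper than a full SVD.

One behaviour of surrogate-variable adjustment deserves emphasis because it
shapes what the method can and cannot find: any latent factor whose
variance footprint rises above the permutation noise floor will be absorbed
— SVA cannot tell "technical" from "biological" structure by itself. A
confounder phenotype that shifts only a handful of CpGs stays invisible on
a realistically sized array (its single-factor eigenvalue sits below the
noise floor of a 10,000+-probe matrix) and its signal survives to be
harvested; the same confounder planted on a toy array of a few hundred
probes would be detected and adjusted away. The synthetic study conditions
below therefore use array sizes of 10,000+ probes whenever
surrogate-variable estimation is in the loop — this is fidelity to real
array geometry, not a tuning knob.

## Case definitions

Status derivation uses "ever" semantics over repeated questionnaire waves:
any wave with the symptom reported *and* a doctor visited makes a case;
reporting the symptom without ever visiting a doctor makes the less-severe
stratum; never reporting it (or reporting only "mild" severity at the
age-15 wave, when that rule is on) makes a control. A doctor answer missing
after a symptom report counts as "no visit" for that wave — conservative,
and the same choice applies to samples whose doctor answer is missing at
every wave (they land in the less-severe stratum; the source material does
not specify this case, so it is a package decision). Sensitivity variants
are parameter changes, not new code: a comorbidity exclusion list, treating
the less-severe stratum as the case group in the testing phase, and
excluding samples whose first report postdates their methylation
measurement.

## Catalog harvest and the testing battery

Hits are looked up in the catalog twice: by CpG id (exact) and by resident
gene symbol (case-insensitive, every symbol of a multi-gene probe). Trait
names are whitespace-normalised and case-folded before deduplication, and a
trait found at both levels keeps CpG-level provenance, so the CpG-level and
additional-gene-level tallies partition the candidate set. An optional
Fisher's-exact enrichment (two-sided, hypergeometric; cross-product odds
ratio with 0.5 continuity only when a cell is zero) is provided for users
worried about heavily studied traits dominating the catalog, but is not
part of the default pipeline — with hit counts this small, a trait list is
the honest output.

The battery fits, per candidate phenotype and condition, an unadjusted and
an adjusted logistic regression (socioeconomic position and age at menarche
in months as adjusters, linear in months). Continuous exposures are
z-scored *within each model's complete-case sample* so odds ratios are per
SD and comparable across scales. Eligibility uses the "fewer than five"
rule strictly: a binary exposure needs every cell of its non-missing
2x2 with the condition to hold at least five participants, a continuous one
needs five non-missing values in each group; exactly five passes.
Percentages in the summary table use the *full* group size — missing
included — as denominator, the single most error-prone convention when
reproducing printed cohort tables (445/641 = 69.4%), and display rounding
is half-up at one decimal. Perfect separation and non-convergence yield an
omitted row with a reason, never a silent estimate.

## The synthetic-data generator

The generator is the package's study system. Per sample it draws a
standard-normal confounder $U$, assigns case status by
$\mathrm{logit}\,P(\mathrm{case}) = \mathrm{logit}(0.15) + 1.0\,U$
(prevalence matching an adolescent menstrual-symptom cohort; one log-odds
unit per SD is a strong but realistic lifestyle confounder), and assigns a
two-level batch, optionally correlated with case status
(`batch_case_assoc`) to emulate plate-assignment confounding. Probes are
null except for three planted roles: *direct* probes shifted by case
status, *confounded* probes shifted by $0.05\,U$ (beta-scale per SD), and
*batch* probes shifted by 0.05 in the second batch; independent Gaussian
noise (SD 0.02) is added and values are clipped to $[0,1]$. Gaussian noise
on the beta scale, rather than a logit-normal model, is sufficient for the
rank and threshold behaviour under test, because baselines are kept away
from the boundary. Confounding is always planted as a common cause
($U \to \text{methylation}$, $U \to \text{case}$), never as mediation —
that is the structure the method claims to leverage. One seed drives
everything; identical seeds give byte-identical output.

What the generator does not emulate: co-methylation blocks and LD
structure, dye-bias or normalisation artefacts, realistic per-probe
variance heterogeneity, caregiver-vs-self reporting effects. Passing tests
on this generator therefore demonstrate the pipeline's *mechanics* — that
planted structure of each kind is recovered, masked, or adjusted as
designed — not its power or calibration on real arrays.

## Study conditions used by the checks

The test suite and the acceptance script run at sizes chosen to finish on a
single CPU while keeping each check's statistics meaningful; each scenario
states its conditions explicitly:

* **null calibration** — 200 samples x 5,000 probes, no planted effects,
  10 seeds: fraction of $p<0.05$ inside its binomial 99% interval and
  $\lambda \in [0.9, 1.1]$;
* **batch recovery / inflation reduction** — 200 samples x 2,000-3,000
  probes, one batch factor on half the probes (effect 0.1 vs noise 0.02),
  batch-case association 0.3, 10 seeds: $|r(\mathrm{SV}_1,
  \mathrm{batch})| \ge 0.8$ and $\lambda$ reduced by adjustment. The
  association is what makes inflation happen at all — an
  exposure-orthogonal batch factor only adds outcome variance and
  *deflates* $\lambda$;
* **end-to-end confounder recovery** — 400 samples x 10,000 probes, five
  confounded probes (0.05 per SD, log-odds 1.0), 600 batch probes, 10
  seeds: the planted trait appears in the final association table with an
  odds ratio above 1;
* **OLS / logistic / Fisher closed forms** — against independently coded
  oracles (normal equations + t distribution, Newton-Raphson,
  hypergeometric enumeration) at 1e-10 / 1e-8 / 1e-12.

## Known limitations

The catalog can only return traits someone has already studied, and heavily
studied traits (smoking above all) are over-represented; gene-level look-ups
over-weight long genes. The minimally adjusted scan will surface technical
artefacts if surrogate-variable adjustment is disabled, and will absorb
*broad* biological confounders (cell composition-scale footprints) into the
surrogate variables. The less-severe and doctor-visit definitions encode
care-seeking behaviour as much as symptom severity. None of the battery's
odds ratios are causal estimates.
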