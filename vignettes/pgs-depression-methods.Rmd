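---
title: "Methods: candidate-panel polygenic scores for quantitative depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-panel polygenic scores for quantitative depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprpgs)
```

# Overview

`deprpgs` implements a complete candidate-gene polygenic score (PGS)
pipeline for a quantitative depression outcome (BDI-II, an integer score
on 0--63) measured together with social and demographic covariates in a
population cohort.  The pipeline has five analysis stages plus a
synthetic data generator:

1. **I/O and harmonization** — genotype import (dosage TSV, VCF, PLINK
   text ped/map), effect-allele orientation, and reconciliation of
   external summary-statistic weights against a local panel.
2. **Variant quality control** — call rate, minor allele frequency
   (MAF), a Hardy--Weinberg equilibrium (HWE) exact test, and
   linkage-disequilibrium (LD) proxy pruning.
3. **Association** — per-variant covariate-adjusted linear regression
   and a Mann--Whitney screen of binary social factors with a
   Bonferroni-corrected threshold.
4. **Scoring** — weighted and unweighted PGS construction with
   negative-effect recoding.
5. **Modeling** — four nested linear models decomposing the variance in
   depression explained by the PGS and by social factors, with AIC-based
   backward elimination.

Every stage is exercised by a synthetic cohort generator so the whole
analysis is reproducible and testable without access to individual-level
human data.

# The polygenic score

For individual $i$ the weighted score is

$$\mathrm{PGS}_i = \sum_{j=1}^{m} w_j \, x_{ij},$$

where $x_{ij} \in \{0, 1, 2\}$ is the dosage of the *scoring allele* of
variant $j$ and $w_j \ge 0$ its weight.  Published per-allele effects
$\beta_j$ may be negative (the effect allele is protective).  Rather
than adding signed terms, `build_weights()` recodes each negative term
onto the other allele:

$$\beta_j x_{ij} = \beta_j \cdot 2 - \beta_j (2 - x_{ij})
  \quad\Longrightarrow\quad
  w_j = |\beta_j|, \; x'_{ij} = 2 - x_{ij},$$

i.e. it counts the *non-effect* allele with weight $|\beta_j|$.  The two
conventions differ only by the additive constant $2\sum_{\beta_j<0}
\beta_j$, so every regression $R^2$, slope test and model comparison is
invariant to the recoding; the recoded form keeps all weights
non-negative so that a higher score always means a genetically higher
predicted depression level.  The **unweighted** score sets every
$w_j = 1$ with the same allele orientation, counting risk alleles.

`score_individuals()` handles missing genotypes by either mean-dosage
imputation (`missing_policy = "mean_dosage"`, the default: a missing
dosage contributes the variant's cohort mean oriented dosage) or by
skipping the variant for that individual (`"skip"`, with the number of
variants actually used reported per individual).

# Quality control

`run_qc()` applies four gates in a fixed order and records every
decision in a ledger (`qc_report`), one row per input variant:

1. **Call rate** $> 0.98$ (proportion of non-missing genotypes).
2. **MAF** $> 0.05$, with the MAF computed from the observed
   effect-allele frequency as $\min(\mathrm{EAF}, 1-\mathrm{EAF})$.
3. **HWE exact test** at $\alpha = 0.05$: the conditional probability,
   given the observed allele counts, of a heterozygote count at most as
   probable as the observed one.  The null distribution is the
   conditional distribution of the heterozygote count $h$ given allele
   count $n_A$ under random mating,
   $$P(h \mid n, n_A) \propto
     \frac{2^{\,h}\, n!}{\left(\frac{n_A - h}{2}\right)!\, h!\,
       \left(n - \frac{n_A+h}{2}\right)!},$$
   computed in log space with `lfactorial()` and normalized, so the
   test is exact for any sample size.  A chi-squared variant
   (`hwe_method = "chisq"`) is provided for comparison.
4. **LD proxy pruning**: among surviving variants that share a
   `locus_label`, pairs with $r^2 \ge 0.2$ are pruned to one member.
   The $r^2$ is the haplotype-frequency correlation estimated from
   unphased genotypes by an EM algorithm (`ld_r2(method = "em")`) that
   resolves double heterozygotes by iterated expected phase, the
   standard approach for unphased data; a genotype-correlation
   estimator is available as `method = "genotype"`.  Which member of a
   pruned pair survives is controlled by `proxy_keep` (an explicit
   keep-list) or, failing that, by a preliminary association pass that
   retains the member more associated with the outcome.

On the bundled study-scale design (32 candidate variants: 30
association candidates, 2 spiked HWE violators, 3 intra-locus LD pairs
with a keep-list) this cascade retains exactly 27 scorable variants.

# Association and screening

`fit_snp_regression()` fits, for each variant, ordinary least squares of
the depression score on the effect-allele dosage plus covariates (sex,
age and ethnicity by default) and reports the per-allele slope, its
standard error and p-value.  Variants whose dosage has no variance after
exclusions are flagged `degenerate` rather than silently given a zero
effect.

`mannwhitney_screen()` compares depression between the two levels of
each binary social factor with the two-sided Mann--Whitney U test: exact
when both groups have at most 8 observations and the data are tie-free,
otherwise the normal approximation with tie and continuity correction.
Significance is declared against the Bonferroni per-test bound
$\alpha/m$; `correction_threshold(0.05, 8)` gives $0.00625$, displayed
as $0.0063$ (half-up rounding to two significant figures).

# Nested models

`run_model_suite()` fits four nested linear models of depression:

| Model | Terms |
|-------|-------|
| 1 | PGS |
| 2 | sex + age + ethnicity |
| 3 | PGS + sex + age + ethnicity |
| 4 | Model 3 + social candidates, reduced by backward elimination |

The social candidates are family income, full-family rearing, childhood
maltreatment, and the four dichotomized Parental Bonding Instrument
(PBI) categories (maternal/paternal care and protection, cut at
27.0/13.5 maternal and 24.0/12.5 paternal care/protection; scores at or
above the cut-off are "high").  Backward elimination removes one
candidate at a time while the Akaike information criterion decreases,
with the Model 3 terms forced to stay; the AIC convention is
$n \log(\mathrm{RSS}/n) + 2(k + 2)$, which differs from `stats::AIC()`
only by a data-independent constant and therefore selects identical
models.  The suite runs each of the two scoring modes (weighted,
unweighted) in the full cohort and in the women-only subgroup (where
`sex` is dropped from the design), and reports the adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-k-1)$ grid across the four models.

Note that when the same cohort supplies both the per-SNP weights and
the model fit, the Model 1 fit is *in-sample* and its $R^2$ is inflated
by roughly $m/n$ relative to the out-of-sample predictive value of the
score; the package's tests verify this inflation directly with
split-half replication.  Reported variance shares should therefore be
read as descriptive decompositions, not as out-of-sample prediction
accuracy.

# Synthetic cohort generator

`sim_config()` + `simulate_cohort()` draw a complete cohort from an
explicit generative model:

* **Genotypes.**  Unlinked variants are drawn from Hardy--Weinberg
  proportions at the configured EAF, optionally perturbed by an
  inbreeding coefficient $F$ so that $P(\mathrm{het}) = 2pq(1-F)$ —
  this is how HWE-violating variants are spiked.  LD pairs are drawn as
  random unions of gametes from a two-locus haplotype distribution
  whose disequilibrium $D = \sqrt{r^2 \, p_A q_A p_B q_B}$ realizes the
  target haplotype $r^2$ (with an explicit feasibility check against
  the Fréchet bounds).  Genotypes are masked missing independently at a
  configurable rate (default 0.002).
* **Covariates.**  Sex, ethnicity, income, family and maltreatment
  indicators follow configured category probabilities; age is uniform
  on 18--25; raw PBI scales are normals positioned so the dichotomized
  "high" categories hit their target prevalences after integer
  rounding, then clamped to the instrument ranges (0--36 care, 0--39
  protection).
* **Phenotype.**  A latent score is the sum of an intercept, per-allele
  SNP effects, covariate effects and Gaussian noise (default SD 6.5);
  the observed BDI-II value is the latent score rounded and clipped to
  $[0, 63]$.  The intercept is solved analytically so the latent mean
  hits a target (default 8.3).  Clipping at the floor mildly attenuates
  variances when the mean is near 0; simulation studies in the test
  suite that need exact variance arithmetic place the intercept
  mid-range instead.

Every draw is a pure function of the configuration seed: each variant,
pair, and stage uses a deterministic derived seed, so cohorts are fully
reproducible and individual variants can be redrawn independently.

## Conditioning on the design

At $\alpha = 0.05$ and $n = 1065$, an unconditioned draw of 30
equilibrium variants has roughly a 70% chance of at least one false
HWE rejection, so "the QC keeps exactly 27 of 32 variants" would not be
a deterministic property of raw sampling.  `simulate_study_cohort()`
therefore samples from the generative law *conditioned on the design
targets*: each variant is redrawn (under deterministic derived seeds)
until the realized data show the designed QC outcome — the two spiked
violators fail the exact test, every other variant passes all gates,
and each LD pair's estimated $r^2$ lands within 0.05 of its target and
above the pruning threshold.  This is rejection sampling from a
conditional distribution, not post-hoc editing of data; set
`condition_on_design = FALSE` for unconditioned draws.

# Scope and limitations

* The generator is additive and cross-sectional: no gene--gene or
  gene--environment interaction terms, no LD beyond the configured
  pairs, no population stratification beyond the ethnicity factor.
* The phenotype model treats the BDI-II as an interval scale; floor
  effects are represented only through rounding and clipping.
* The EM $r^2$ assumes random mating within the sample when resolving
  phase; under strong inbreeding the genotype-correlation estimator is
  the more defensible choice.
* Typical problem sizes are small (tens of variants, $10^3$--$10^4$
  individuals); all algorithms are vectorized but none is engineered
  for biobank-scale data.

# A worked example

```{r example, eval = FALSE}
bundle <- simulate_study_cohort(seed = 1)
qc <- run_qc(bundle$panel, proxy_keep = candidate_ld_pairs()$keep)
n_variants(qc$panel)                 # 27

screen <- mannwhitney_screen(
  bundle$cohort,
  c("sex", "income", "full_family", "maltreatment",
    "maternal_care_cat", "maternal_protection_cat",
    "paternal_care_cat", "paternal_protection_cat"))
attr(screen, "threshold")$displayed  # 0.0063

assoc <- fit_snp_regression(qc$panel, bundle$cohort)
suite <- run_model_suite(qc$panel, bundle$cohort, assoc = assoc)
suite$adjusted_r2
```
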