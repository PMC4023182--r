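---
title: "Methylation-by-genotype interaction screening: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-by-genotype interaction screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(th2screen)
```

## The screening model and its assumptions

The unit of analysis is a within-gene CpG × SNP pair. For each pair the
package fits, by maximum likelihood,

$$\operatorname{logit} P(Y = 1) = \beta_0 + \beta_m M + \sum_j \beta_j
\mathbf{1}[G = j] + \sum_j \gamma_j M\,\mathbf{1}[G = j],$$

where $Y$ is binary asthma status at one age, $M$ the logit-transformed
methylation proportion (M-value) of the CpG at that age, and $G$ the
unordered genotype category of the SNP. The assumptions this inherits are
those of ordinary logistic regression: independent subjects, a linear
log-odds in $M$ within genotype strata, and genotype treated as a factor
— deliberately *not* an allele-dosage trend, because the reported
scientific quantity is the per-genotype contrast against a reference
level, and dominance patterns in cytokine-pathway genes are not assumed
additive.

Several structural choices deserve justification:

* **Analysis scale.** All regressions and t-tests run on the logit
  (M-value) scale. Beta values live on $[0,1]$ with strongly
  heteroskedastic, boundary-compressed noise; the logit transform makes
  variances more comparable and linear modelling defensible. Betas are
  clamped to $[\varepsilon, 1-\varepsilon]$ before transforming so that
  boundary values stay finite; $\varepsilon$ defaults to $10^{-6}$, which
  moves no realistic array value (a 450K beta of exactly 0 or 1 is a
  degenerate measurement, not biology) while bounding M-values at
  $\pm 13.8$.
* **Reference genotype.** The reference level is the most frequent
  genotype among the analysis rows, overridable per SNP. No published
  convention was available; most-frequent maximises the information in
  the reference stratum and makes contrasts against it best-estimated.
  Ties break alphabetically for determinism.
* **Complete cases.** Rows missing outcome, methylation or genotype are
  excluded per model. Genotype levels left with zero observations are
  dropped from the design and reported as NA strata rather than silently
  collapsed — sparse categories are a scientific finding here, not a
  nuisance.
* **Separation.** With rare genotypes and modest samples,
  quasi-complete separation is common: estimates diverge, Wald SEs
  explode, p-values approach 1. The package flags any term with
  $|\hat\beta| > 10$ or $\mathrm{SE} > 50$ (log-OR units; $e^{10}$ is
  already a biologically absurd odds ratio) but still reports it, because
  the goal is a faithful screen, not a corrected estimate. Flagged terms
  cannot trigger selection (configurable). Firth-type penalisation is a
  deliberate non-goal: the screen's stability control is the bootstrap,
  not a different estimator.
* **Convergence.** IRLS runs to a deviance change below $10^{-8}$ with at
  most 100 iterations; non-convergence is recorded on the fit and treated
  as non-selection, never raised as an error.

## Selection rule and multiplicity

A model is a candidate if the methylation main effect *or any single*
interaction contrast has a two-sided Wald p below the screening level
α. The per-contrast rule (rather than a joint test of the interaction
block) is what reproduces per-row significance reporting in this study
design; a joint Wald test over all interaction contrasts is available
behind the `joint_interaction` flag of `select_models()`.

No false-discovery-rate correction is applied, on purpose. The pathway
restriction makes tests dependent, so the design instead (i) lowers α to
0.01 for the main screen and (ii) uses bootstrap selection frequency as
the stability control. With $k$ interaction contrasts per model the
per-model null selection rate is bounded between $\alpha$ and
$(1+k)\alpha$; the package's type-I study (`typeI_error_study()`)
verifies the screen operates inside that union-of-tests band.

## Bootstrap validation

`bootstrap_frequencies()` repeats the *entire* screen on B subject-level
resamples (drawn with replacement, same size as the original). The
resampling unit is the subject: methylation at both ages, genotypes and
outcome travel together, since resampling anything smaller would destroy
the joint distribution the models estimate. Per-replicate seeds derive
deterministically from the master seed (`seed + b`), so a single
replicate can be regenerated in isolation and a fixed
(seed, B, cohort) triple is bit-reproducible. Failed or non-converged
fits count as "not selected" — conservative, and it keeps counts in
$[0, B]$. Retention requires a count strictly above the threshold
(default B/2). Inside every replicate the same α is applied as in the
corresponding original screen (0.05 for the small childhood sample, 0.01
otherwise); whether the original analysis re-applied the two-tier α
inside replicates is not documented anywhere, so the package makes it the
default and leaves it overridable.

## Temporal classification and transition models

Paired t-tests on the logit scale classify each CpG as *dynamic*
(p < 0.05) or *stable* between the ages. The pairing direction is
age 10 − age 18, so positive mean differences read "higher in
childhood". Degenerate inputs are explicit: fewer than 2 pairs gives an
undetermined classification; zero-variance nonzero differences report
p = 0 with a degeneracy flag rather than a fabricated t statistic.

Transition regressions compare one transition group (positive = asthma
incidence, negative = remission) against subjects asthma-free at both
ages; persistent cases are excluded entirely, because the scientific
contrast is "transition vs never". The methylation predictor switches
with the temporal classification: Δ-methylation (age 18 − age 10, so
"increase over time" has positive sign) for dynamic CpGs, age-18
methylation for stable ones. The reported headline effect is the
methylation(-change) main-effect log-OR; genotype and its interaction
stay in the model as the screen defined them.

## The synthetic cohort generator

`simulate_cohort()` exists so every downstream stage is testable without
access to any cohort data. It emulates, per configured defaults:

* **Design**: n = 245 subjects with complete age-18 measurements;
  age-10 methylation observed only for a nested case-control subsample of
  16 asthma cases + 18 controls (a 34-sample childhood analysis set);
  missingness completely at random with small default rates
  (genotype 2%, phenotype 0.4%), giving per-SNP denominators in the
  ~230–240 range out of 245.
* **Genotypes**: independent SNPs in Hardy–Weinberg proportions
  $(q^2, 2pq, p^2)$. The nine SNPs with published genotype tables use
  allele-count MAF estimates from those tables (including a rare-genotype
  SNP with minor-homozygote frequency under 1%); placeholder SNPs cycle
  deterministically over realistic MAFs (0.05–0.45). Linkage
  disequilibrium is not simulated: the analysis never models it, and LD
  only matters here as an interpretive caveat.
* **Methylation**: per CpG, beta-distributed margins matched by method of
  moments ($a = m(m(1-m)/s^2 - 1)$, $b = (1-m)(m(1-m)/s^2-1)$) to that
  age's (mean, SD), coupled across ages by a Gaussian copula. The five
  CpGs with published summary moments use them; the rest get
  deterministic array-realistic values (bimodal means near 0.05/0.85,
  SDs 0.01–0.03, slight negative age drift). The between-age correlation
  has no published estimate — only the qualitative statement that highly
  methylated sites stay highly methylated — so ρ defaults to 0.7 and
  should be treated as unanchored. The copula family is configurable
  (`gaussian`, `comonotone`, `independent`); any exchangeable-margin
  coupling would satisfy the stated structure.
* **Outcomes**: per age, Bernoulli with log-odds
  $b_0 + b_m M + b_g[G] + b_{int}[G]\,M$, with baseline prevalences
  11% (age 10) and 14.3% (age 18) and all effects zero by default — the
  default cohort is a global null. The age-18 model optionally takes a
  methylation-change term $b_\Delta (M_{18}-M_{10})$ to drive
  transition-analysis simulations. Outcomes at the two ages are
  conditionally independent given their predictors, matching the fact
  that each age is analysed separately.

What the generator does *not* emulate: array intensities and probe-type
effects, batch structure, cell-composition heterogeneity, LD, and any
dependence between CpGs. Passing tests therefore demonstrate the
statistical machinery operates correctly under the stated data-generating
model — not that real blood methylation data satisfy that model.

## Numerical and degenerate-input choices

* Model enumeration, screen ordering and rank tie-breaks are
  lexicographic in (gene, cpg, snp): all outputs are order-deterministic.
* TSV writers emit doubles with 17 significant digits, so a write/read
  cycle is content-identical and the bootstrap determinism contract
  extends to on-disk reports.
* A genotype monomorphic in the analysis rows collapses the model to the
  methylation-only fit (no contrasts exist); a constant outcome or a
  design with fewer rows than parameters is a per-model error, captured
  by the screen and recorded as a failure rather than raised.
* The nested 16+18 subsample is a conditional design: a simulated cohort
  can, with small probability, contain fewer than 16 childhood cases, and
  the generator then raises a config error rather than silently shrinking
  the draw.
* Chi-square representativeness tests default to *no* continuity
  correction; published two-decimal p-values for this table type are
  internally inconsistent under any single convention, and the headline
  (asthma) row reproduces only without correction. The correction is a
  flag, not a default.

## Problem sizes used in the shipped studies

The packaged simulation studies are sized to be informative yet quick on
a single CPU: the type-I study uses 1,000 independent null models at
n = 500; the recovery study 200 replicates at n = 2,000; the bootstrap
power study B = 100 resamples of an n = 2,000 cohort with one injected
interaction (log-OR 1.5) and eight independent null models in separate
genes — separate genes because within-gene enumeration would otherwise
pair the signal CpG with null SNPs and make those "null" models
marginally non-null. The full design's B = 1,000 changes only the
granularity of the frequency scale, not the machinery, and is available
by argument.

## Known limitations

* Wald inference under separation is reported as-is; confidence
  intervals for flagged terms are meaningless and marked so.
* The bootstrap validates *selection stability*, not effect-size
  calibration; bias-corrected bootstrap intervals are out of scope.
* Covariate adjustment (atopy, IgE, smoking, cell composition) is not
  implemented in the screening or transition models, mirroring the
  analysis design this package operationalises.
* The generator's unpublished-CpG calibration and ρ = 0.7 coupling are
  reasonable defaults, not estimates; conclusions about real data should
  never rest on them.
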