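# th2screen

Pathway-based screening of DNA methylation × genotype interaction effects
on asthma, with bootstrap model validation and longitudinal
methylation/asthma-transition analysis.

## The problem

In candidate-gene epigenetics, the effect of CpG methylation on a disease
outcome can depend on nearby genetic variants. For the T-helper-2 (Th2)
cytokine pathway — the genes *IL4*, *IL4R*, *IL13*, *GATA3* and *STAT6* —
this package screens every within-gene CpG × SNP pair for such
interactions on binary asthma status measured at two ages (10 and 18
years), asking three questions:

1. Which CpG × SNP models show a methylation main effect or a
   methylation-by-genotype interaction on asthma at each age?
2. Which of those models are stable under resampling (bootstrap selection
   frequency), rather than artefacts of sparse genotype strata?
3. Does methylation *change* between the ages at the implicated CpGs, and
   is that change associated with asthma transition (incidence or
   remission) during adolescence?

## The model

For each gene g, every probe–variant pair (c, s) within g is fit by
logistic regression on the logit (M-value) methylation scale:

    logit P(asthma = 1) = β₀ + β_m · M_c + Σ_j β_j · 1[G_s = j]
                        + Σ_j γ_j · M_c · 1[G_s = j]

where `M_c = log(β_c / (1 − β_c))` is the clipped logit of the beta value
and genotype enters as unordered indicator contrasts against a reference
level (the most frequent genotype). A model is a *candidate* if its
methylation main effect or any interaction contrast is significant at the
screening level α (0.01; 0.05 in small samples). Candidates are validated
by refitting the whole screen in B = 1,000 subject-level bootstrap
resamples and retaining models selected in more than B/2 of them.
Quasi-complete separation (huge |log-OR| with Wald p ≈ 1, a fact of life
with rare genotypes) is flagged, reported, and barred from triggering
selection.

CpGs in retained models are classified *stable* or *dynamic* between the
ages by paired t-tests on the logit scale; transition regressions then
model positive transition (asthma-free at 10 → asthma at 18) and negative
transition (remission) against no-asthma-at-both-ages, using the
methylation change Δ M = M₁₈ − M₁₀ for dynamic CpGs and M₁₈ for stable
ones, again with genotype and its interaction.

Because no individual-level cohort data are distributable, the package
ships a calibrated synthetic cohort generator: Hardy–Weinberg genotypes,
beta-distributed methylation matched to published per-CpG moments by
method of moments and coupled across ages by a Gaussian copula, logistic
outcome models, completely-at-random missingness, and the nested age-10
case-control design (16 cases + 18 controls with childhood methylation out
of n = 245).

## Worked example

```r
library(th2screen)

panel <- th2_panel()
panel_counts(panel)
#>    gene n_cpgs n_snps n_models
#> 1 GATA3     67     17     1139
#> 2  IL13      9      7       63
#> 3   IL4      5      4       20
#> 4  IL4R     10     13      130
#> 5 STAT6      9      1        9

cohort <- simulate_cohort(cohort_config(n = 245), seed = 7)
cohort
#> Two-timepoint cohort: 245 samples
#>   methylation: 100 CpGs (age 18: 245 samples; age 10 complete rows: 34)
#>   genotypes:   42 SNPs
#>   asthma:      age10 42 cases / age18 41 cases
#>   simulated cohort (truth record attached)

screen18 <- run_screen(cohort, panel, age = "age18", alpha = 0.01)
screen18
#> CpG x SNP interaction screen [age18], alpha = 0.01
#>   1361 models fit (0 failures), 14 selected
#>   gene        cpg        snp          trigger       p_meth    p_int_min
#>  GATA3 cg90000030 rs99000023 methylation_main 0.0054750376 0.0177731441
#>  ...
```

The default cohort is simulated under the global null (no true effects),
so the 14 selections out of 1,361 models (~1%) are exactly the false
positives the screening level implies — and the bootstrap step shows none
of them is stable. Restricting to *IL4* for speed:

```r
il4 <- panel_definition(panel$cpgs[panel$cpgs$gene == "IL4", ],
                        panel$snps[panel$snps$gene == "IL4", ])
bootstrap_frequencies(cohort, il4, age = "age18", alpha = 0.01,
                      B = 100, seed = 7)
#> Bootstrap model validation [age18]: B = 100, alpha = 0.01, retention count > 50
#>  rank gene        cpg        snp count   B passes_threshold
#>     1  IL4 cg90000003 rs99000001    31 100            FALSE
#>     2  IL4 cg90000001  rs2243250    26 100            FALSE
#>     ...
```

No model clears the retention threshold: under the null nothing is
reproducibly selected. Injecting a true interaction
(`outcome_model(b_int = ...)` in `cohort_config()`) makes the
corresponding model the top-ranked, threshold-passing one — see
`bootstrap_power_study()` and the methods vignette.

Longitudinal stage, for one CpG:

```r
dyn <- methylation_dynamics(cohort, "cg26937798")
transition_regression(cohort, "cg26937798", "rs3024685", dyn, "positive")
```

A `th2_cli()` front end (`inst/cli/th2screen.R`) exposes the stages as
subcommands (`simulate`, `screen`, `bootstrap`, `temporal`, `transition`,
`table1`, `all`) with TSV outputs and a reproducibility manifest.

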