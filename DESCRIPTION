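Package: th2screen
Title: Pathway-Based Screening of DNA Methylation by Genotype
    Interactions on Asthma Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate-gene screening of CpG methylation by SNP genotype
    interaction effects on binary asthma status in the Th2 cytokine
    pathway (IL4, IL4R, IL13, GATA3, STAT6). Fits, per within-gene CpG x
    SNP pair, a logistic regression of asthma on logit-transformed
    methylation (M-values), categorical genotype and their interaction,
    with quasi-complete-separation flagging; applies a significance-based
    selection rule; validates selected models by subject-level bootstrap
    selection frequencies; classifies CpGs as temporally stable or
    dynamic by paired t-tests between two ages and fits asthma-transition
    regressions on methylation change; and includes a calibrated
    synthetic two-timepoint cohort generator (Hardy-Weinberg genotypes,
    beta-distributed methylation linked across ages by a Gaussian
    copula, logistic outcome models, nested case-control subsampling)
    so the whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
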