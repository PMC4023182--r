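#' Type-I error study for the selection rule
#'
#' Simulates a global-null cohort in which every model is truly null and
#' measures the per-model selection rate of the screen. The model space is
#' laid out as independent single-CpG / single-SNP genes, so the screened
#' models are mutually independent null tests. Because selection fires on
#' the methylation main effect OR any of k interaction contrasts, the rate
#' is expected between `alpha` and `(1+k) * alpha` (union-of-tests bound).
#'
#' @param n cohort size.
#' @param n_models number of independent null models.
#' @param alpha screening level.
#' @param maf shared minor allele frequency.
#' @param prevalence outcome prevalence.
#' @param seed master seed.
#' @return list with `rate` (selection proportion), `n_fitted`, `k`
#'   (interaction contrasts per model), `alpha`.
#' @export
typeI_error_study <- function(n = 500, n_models = 1000, alpha = 0.01,
                              maf = 0.3, prevalence = 0.143, seed = 1L) {
  genes <- sprintf("g%04d", seq_len(n_models))
  panel <- panel_definition(
    cpgs = data.frame(gene = genes, probe = sprintf("cgN%06d", seq_len(n_models)),
                      chrom = "1", pos = 1000L + seq_len(n_models),
                      region = "Body", stringsAsFactors = FALSE),
    snps = data.frame(gene = genes, snp = sprintf("rsN%06d", seq_len(n_models)),
                      allele1 = "A", allele2 = "G", stringsAsFactors = FALSE))
  cfg <- cohort_config(
    panel = panel, n = n,
    maf = stats::setNames(rep(maf, n_models), panel$snps$snp),
    moments = data.frame(probe = panel$cpgs$probe, mean10 = 0.5, sd10 = 0.1,
                         mean18 = 0.5, sd18 = 0.1),
    outcome18 = outcome_model(b0 = stats::qlogis(prevalence)),
    missing = list(beta = 0, genotype = 0, phenotype = 0), subsample = NULL)
  co <- simulate_cohort(cfg, seed = seed)
  scr <- run_screen(co, panel, age = "age18", alpha = alpha)
  fitted <- vapply(scr$fits, inherits, logical(1), what = "th2_fit")
  list(rate = sum(scr$selection$selected) / sum(fitted),
       n_fitted = sum(fitted), k = 2L, alpha = alpha)
}

#' Interaction-effect recovery study
#'
#' Repeatedly simulates a cohort with a known methylation-by-genotype
#' interaction (same log-OR for both minor-allele genotypes) and refits the
#' screen's model, recording the heterozygote interaction contrast. Reports
#' the mean bias and the empirical coverage of the 95% Wald interval.
#'
#' @param b_int true interaction log-OR.
#' @param maf minor allele frequency.
#' @param n cohort size per replicate.
#' @param reps number of replicates.
#' @param seed master seed (replicate r uses `seed + r`).
#' @return list with `bias`, `coverage`, `estimates`, `ses`, `truth`.
#' @export
recovery_study <- function(b_int = 1.0, maf = 0.3, n = 2000, reps = 200,
                           seed = 1L) {
  panel <- panel_definition(
    cpgs = data.frame(gene = "G1", probe = "cgR000001", chrom = "1",
                      pos = 1001L, region = "Body", stringsAsFactors = FALSE),
    snps = data.frame(gene = "G1", snp = "rsR000001", allele1 = "A",
                      allele2 = "G", stringsAsFactors = FALSE))
  cfg <- cohort_config(
    panel = panel, n = n, maf = c(rsR000001 = maf),
    moments = data.frame(probe = "cgR000001", mean10 = 0.5, sd10 = 0.1,
                         mean18 = 0.5, sd18 = 0.1),
    outcome18 = outcome_model(b0 = -1.5, b_m = 0.4,
                              b_g = c(AG = 0.3, AA = 0.3),
                              b_int = c(AG = b_int, AA = b_int),
                              cpg = "cgR000001", snp = "rsR000001"),
    missing = list(beta = 0, genotype = 0, phenotype = 0), subsample = NULL)
  est <- se <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(cfg, seed = seed + r)
    mv <- beta_to_mvalue(co$beta18)
    fit <- fit_interaction_model(co$phenotypes$asthma18, mv[, "cgR000001"],
                                 unclass(co$genotypes)[, "rsR000001"],
                                 reference = "GG")
    j <- match("meth:geno=AG", fit$terms$term)
    est[r] <- fit$terms$estimate[j]
    se[r] <- fit$terms$se[j]
  }
  z <- stats::qnorm(0.975)
  list(bias = mean(est) - b_int,
       coverage = mean(abs(est - b_int) <= z * se),
       estimates = est, ses = se, truth = b_int)
}

#' Bootstrap selection-frequency power study
#'
#' One gene carries a single CpG x SNP pair with an injected interaction;
#' two further genes hold truly null pairs (within-gene enumeration keeps
#' them fully independent of the signal). Bootstrap selection frequencies
#' are computed for all models and the signal's count is compared with the
#' retention threshold `B/2` and with the strongest null model.
#'
#' @param b_int injected interaction log-OR.
#' @param n cohort size.
#' @param B bootstrap samples.
#' @param alpha screening level inside each replicate.
#' @param maf shared minor allele frequency.
#' @param seed master seed.
#' @return list with `signal_count`, `max_null_count`, `B`, `summaries`.
#' @export
bootstrap_power_study <- function(b_int = 1.5, n = 2000, B = 100,
                                  alpha = 0.01, maf = 0.3, seed = 1L) {
  cpgs <- data.frame(
    gene = c("SIG", "NUL1", "NUL1", "NUL2", "NUL2"),
    probe = sprintf("cgB%06d", 1:5), chrom = "1", pos = 1000L + 1:5,
    region = "Body", stringsAsFactors = FALSE)
  snps <- data.frame(
    gene = c("SIG", "NUL1", "NUL1", "NUL2", "NUL2"),
    snp = sprintf("rsB%06d", 1:5), allele1 = "A", allele2 = "G",
    stringsAsFactors = FALSE)
  panel <- panel_definition(cpgs, snps)
  cfg <- cohort_config(
    panel = panel, n = n,
    maf = stats::setNames(rep(maf, 5), snps$snp),
    moments = data.frame(probe = cpgs$probe, mean10 = 0.5, sd10 = 0.1,
                         mean18 = 0.5, sd18 = 0.1),
    outcome18 = outcome_model(b0 = -1.5, b_m = 0.3,
                              b_g = c(AG = 0.2, AA = 0.2),
                              b_int = c(AG = b_int, AA = b_int),
                              cpg = "cgB000001", snp = "rsB000001"),
    missing = list(beta = 0, genotype = 0, phenotype = 0), subsample = NULL)
  co <- simulate_cohort(cfg, seed = seed)
  bt <- bootstrap_frequencies(co, panel, age = "age18", alpha = alpha,
                              B = B, seed = seed)
  s <- bt$summaries
  sig <- s$gene == "SIG"
  list(signal_count = s$count[sig],
       max_null_count = max(s$count[!sig]), B = B, summaries = s)
}

#' Transition-effect recovery study
#'
#' Simulates a cohort whose age-18 asthma status depends on the change of
#' logit methylation at a temporally dynamic CpG (nobody asthmatic at age
#' 10, so every subject is either a positive transition or transition-free),
#' classifies the CpG via the paired t-test, and fits the transition
#' regression.
#'
#' @param b_delta true log-OR per unit methylation change (age18 - age10).
#' @param n cohort size.
#' @param maf minor allele frequency of the accompanying SNP.
#' @param seed master seed.
#' @return list with `estimate`, `se`, `classification`, `truth`.
#' @export
transition_recovery_study <- function(b_delta = -3, n = 2000, maf = 0.3,
                                      seed = 1L) {
  panel <- panel_definition(
    cpgs = data.frame(gene = "G1", probe = "cgT000001", chrom = "1",
                      pos = 1001L, region = "5'UTR", stringsAsFactors = FALSE),
    snps = data.frame(gene = "G1", snp = "rsT000001", allele1 = "A",
                      allele2 = "G", stringsAsFactors = FALSE))
  cfg <- cohort_config(
    panel = panel, n = n, maf = c(rsT000001 = maf),
    moments = data.frame(probe = "cgT000001", mean10 = 0.076, sd10 = 0.022,
                         mean18 = 0.062, sd18 = 0.013),
    rho = 0.7,
    outcome10 = outcome_model(b0 = -30),
    outcome18 = outcome_model(b0 = -1.2, b_delta = b_delta, cpg = "cgT000001"),
    missing = list(beta = 0, genotype = 0, phenotype = 0), subsample = NULL)
  co <- simulate_cohort(cfg, seed = seed)
  dyn <- methylation_dynamics(co, "cgT000001")
  fit <- transition_regression(co, "cgT000001", "rsT000001", dyn, "positive")
  j <- match("meth", fit$terms$term)
  list(estimate = fit$terms$estimate[j], se = fit$terms$se[j],
       classification = dyn$classification, truth = b_delta)
}
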