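#' Method-of-moments beta distribution shapes
#'
#' Matches a beta distribution to a target (mean, SD):
#' `a = m(m(1-m)/s^2 - 1)`, `b = (1-m)(m(1-m)/s^2 - 1)`. Feasibility
#' requires `s^2 < m(1-m)`.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation.
#' @return named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_shape_params(0.076, 0.022)  # ~ (10.95, 133.14)
#' @export
beta_shape_params <- function(mean, sd) {
  if (any(mean <= 0 | mean >= 1)) stop("beta mean must lie in (0, 1)")
  if (any(sd^2 >= mean * (1 - mean)))
    stop("infeasible beta moments: need SD^2 < mean*(1-mean)")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Specify a per-age logistic outcome model
#'
#' Asthma status at one age is drawn Bernoulli with log-odds
#' `b0 + b_m * M + b_g[G] + b_int[G] * M (+ b_delta * (M18 - M10))`, where
#' `M` is the logit methylation of the focal CpG at that age and `G` the
#' genotype category of the focal SNP. Genotype levels not named in `b_g` /
#' `b_int` contribute 0. `b_delta` (methylation change effect, age-18 model
#' only) supports transition-analysis simulations.
#'
#' @param b0 baseline log-odds.
#' @param b_m methylation main effect (log-OR per logit unit).
#' @param b_g named numeric, per-genotype main effects.
#' @param b_int named numeric, per-genotype interaction effects.
#' @param b_delta log-OR per unit change of logit methylation (age18 - age10).
#' @param cpg,snp focal probe / SNP ids (required if any effect beyond `b0`
#'   is non-zero).
#' @return an `outcome_model` list.
#' @export
outcome_model <- function(b0 = 0, b_m = 0, b_g = NULL, b_int = NULL,
                          b_delta = 0, cpg = NULL, snp = NULL) {
  if ((b_m != 0 || length(b_int) || b_delta != 0) && is.null(cpg))
    stop("outcome model with methylation effects needs a focal 'cpg'")
  if ((length(b_g) || length(b_int)) && is.null(snp))
    stop("outcome model with genotype effects needs a focal 'snp'")
  if (length(b_g) && is.null(names(b_g))) stop("b_g must be named by genotype")
  if (length(b_int) && is.null(names(b_int))) stop("b_int must be named by genotype")
  structure(list(b0 = b0, b_m = b_m, b_g = b_g, b_int = b_int,
                 b_delta = b_delta, cpg = cpg, snp = snp),
            class = "outcome_model")
}

#' Configure a synthetic two-timepoint cohort
#'
#' Defaults emulate the study design the analysis assumes: n = 245 young
#' women with age-18 methylation, genotypes and phenotypes; age-10
#' methylation observed only for a nested case-control subsample of 16
#' asthma cases and 18 controls; Hardy-Weinberg genotypes at the panel's
#' minor allele frequencies; beta-distributed methylation matched to
#' per-CpG (mean, SD) at each age, linked across ages by a Gaussian copula
#' with correlation `rho = 0.7`; null outcome models with baseline
#' prevalences 11% (age 10) and 14.3% (age 18).
#'
#' @param panel a [panel_definition()].
#' @param n number of subjects.
#' @param maf named minor-allele-frequency vector over panel SNPs, each in
#'   \[0, 0.5\].
#' @param moments data.frame as [default_beta_moments()]: `probe`, `mean10`,
#'   `sd10`, `mean18`, `sd18`.
#' @param rho between-age methylation correlation (copula parameter) in
#'   \[-1, 1\].
#' @param copula `"gaussian"` (default), `"comonotone"` (ignores `rho`,
#'   perfect rank dependence) or `"independent"`.
#' @param outcome10,outcome18 [outcome_model()] for each age.
#' @param missing list of completely-at-random missingness rates per table:
#'   `beta`, `genotype`, `phenotype`.
#' @param subsample `list(cases =, controls =)` for the nested age-10
#'   methylation draw, or `NULL` to measure age-10 methylation for all.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(panel = th2_panel(), n = 245,
                          maf = default_mafs(panel),
                          moments = default_beta_moments(panel),
                          rho = 0.7,
                          copula = c("gaussian", "comonotone", "independent"),
                          outcome10 = outcome_model(b0 = stats::qlogis(0.11)),
                          outcome18 = outcome_model(b0 = stats::qlogis(0.143)),
                          missing = list(beta = 0, genotype = 0.02,
                                         phenotype = 0.004),
                          subsample = list(cases = 16, controls = 18)) {
  stopifnot(inherits(panel, "panel_definition"), n >= 1)
  copula <- match.arg(copula)
  snps <- panel$snps$snp
  if (!all(snps %in% names(maf)))
    stop("maf must name every panel SNP")
  maf <- maf[snps]
  if (any(maf < 0 | maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  if (!all(panel$cpgs$probe %in% moments$probe))
    stop("moments must cover every panel probe")
  moments <- moments[match(panel$cpgs$probe, moments$probe), , drop = FALSE]
  for (age in c("10", "18")) {
    m <- moments[[paste0("mean", age)]]; s <- moments[[paste0("sd", age)]]
    bad <- which(m <= 0 | m >= 1 | s^2 >= m * (1 - m))
    if (length(bad))
      stop("infeasible beta moments at age ", age, " for CpG(s): ",
           paste(moments$probe[bad], collapse = ", "))
  }
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  for (om in list(outcome10, outcome18)) {
    stopifnot(inherits(om, "outcome_model"))
    if (!is.null(om$cpg) && !om$cpg %in% panel$cpgs$probe)
      stop("outcome model focal CpG not in panel: ", om$cpg)
    if (!is.null(om$snp)) {
      k <- match(om$snp, panel$snps$snp)
      if (is.na(k)) stop("outcome model focal SNP not in panel: ", om$snp)
      cats <- genotype_categories(panel$snps$allele1[k], panel$snps$allele2[k])
      cats <- vapply(strsplit(cats, ""), function(a) paste0(sort(a), collapse = ""),
                     character(1))
      bad <- setdiff(c(names(om$b_g), names(om$b_int)), cats)
      if (length(bad))
        stop("outcome model names genotype level(s) not implied by the allele pair of ",
             om$snp, ": ", paste(bad, collapse = ", "))
    }
  }
  rates <- c(beta = 0, genotype = 0, phenotype = 0)
  rates[names(missing)] <- unlist(missing)
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  if (!is.null(subsample)) {
    stopifnot(is.numeric(subsample$cases), is.numeric(subsample$controls),
              subsample$cases >= 1, subsample$controls >= 1,
              subsample$cases + subsample$controls <= n)
  }
  structure(list(panel = panel, n = as.integer(n), maf = maf,
                 moments = moments, rho = rho, copula = copula,
                 outcome10 = outcome10, outcome18 = outcome18,
                 missing = as.list(rates), subsample = subsample),
            class = "cohort_config")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' SNPs are independent; per SNP the three genotype categories are drawn
#' with probabilities (q^2, 2pq, p^2) for minor allele frequency q.
#'
#' @param maf named minor-allele-frequency vector, each in \[0, 0.5\].
#' @param n number of subjects.
#' @param alleles named list of `c(minor, major)` allele pairs over the
#'   same SNPs, or a [panel_definition()] covering them.
#' @param sample_ids optional ids (default `S0001`, ...).
#' @param seed optional; when given, seeds the RNG first.
#' @return a [genotype_table()].
#' @export
simulate_genotypes <- function(maf, n, alleles, sample_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(maf < 0 | maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  if (inherits(alleles, "panel_definition")) {
    p <- alleles
    alleles <- stats::setNames(
      lapply(seq_len(nrow(p$snps)), function(i) c(p$snps$allele1[i], p$snps$allele2[i])),
      p$snps$snp)
  }
  snps <- names(maf)
  if (!all(snps %in% names(alleles))) stop("alleles must cover every SNP in maf")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  out <- matrix(NA_character_, n, length(snps),
                dimnames = list(sample_ids, snps))
  for (j in seq_along(snps)) {
    a <- alleles[[snps[j]]]
    cats <- genotype_categories(a[1], a[2])
    cats <- vapply(strsplit(cats, ""), function(x) paste0(sort(x), collapse = ""),
                   character(1))
    q <- maf[j]
    out[, j] <- sample(cats, n, replace = TRUE,
                       prob = c(q^2, 2 * q * (1 - q), (1 - q)^2))
  }
  genotype_table(out)
}

#' Simulate paired-age methylation beta matrices
#'
#' Per CpG, the two ages are linked by a copula on the latent uniform scale
#' and each margin is a beta distribution matched by method of moments to
#' that age's (mean, SD) ([beta_shape_params()]). The Gaussian copula uses
#' correlation `rho`; `rho = 1` reduces to the comonotone coupling
#' (identical ranks at both ages).
#'
#' @param n number of subjects.
#' @param moments data.frame with `probe`, `mean10`, `sd10`, `mean18`, `sd18`.
#' @param rho copula correlation in \[-1, 1\].
#' @param copula `"gaussian"`, `"comonotone"` or `"independent"`.
#' @param sample_ids optional ids.
#' @param seed optional; when given, seeds the RNG first.
#' @return list with [beta_matrix()] elements `beta10`, `beta18`.
#' @export
simulate_methylation <- function(n, moments, rho = 0.7,
                                 copula = c("gaussian", "comonotone", "independent"),
                                 sample_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copula <- match.arg(copula)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  p <- nrow(moments)
  b10 <- matrix(NA_real_, n, p, dimnames = list(sample_ids, moments$probe))
  b18 <- b10
  for (j in seq_len(p)) {
    s10 <- beta_shape_params(moments$mean10[j], moments$sd10[j])
    s18 <- beta_shape_params(moments$mean18[j], moments$sd18[j])
    z1 <- stats::rnorm(n)
    z2 <- switch(copula,
      gaussian = rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n),
      comonotone = z1,
      independent = stats::rnorm(n))
    b10[, j] <- stats::qbeta(stats::pnorm(z1), s10[1], s10[2])
    b18[, j] <- stats::qbeta(stats::pnorm(z2), s18[1], s18[2])
  }
  list(beta10 = beta_matrix(b10, "age10"), beta18 = beta_matrix(b18, "age18"))
}

#' Simulate binary outcomes from a logistic model
#'
#' @param model an [outcome_model()].
#' @param mvalues named numeric vector of focal-CpG logit methylation (may
#'   be `NULL` for intercept-only models).
#' @param genotypes named character vector of focal-SNP genotype categories
#'   (may be `NULL`).
#' @param mdelta named numeric vector of methylation change (age18 - age10)
#'   for the focal CpG; needed only when `model$b_delta != 0`.
#' @param n number of subjects (required for intercept-only models without
#'   `mvalues`/`genotypes`).
#' @param sample_ids optional ids.
#' @param seed optional; when given, seeds the RNG first.
#' @return named integer 0/1 vector.
#' @export
simulate_outcomes <- function(model, mvalues = NULL, genotypes = NULL,
                              mdelta = NULL, n = NULL, sample_ids = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "outcome_model"))
  if (is.null(n))
    n <- length(if (!is.null(mvalues)) mvalues else genotypes)
  if (n < 1L) stop("cannot simulate outcomes for an empty cohort")
  if (is.null(sample_ids))
    sample_ids <- names(if (!is.null(mvalues)) mvalues else genotypes)
  eta <- rep(model$b0, n)
  if (model$b_m != 0 || length(model$b_int)) {
    if (is.null(mvalues)) stop("model has methylation effects but no mvalues given")
    eta <- eta + model$b_m * mvalues
  }
  if (length(model$b_g)) {
    if (is.null(genotypes)) stop("model has genotype effects but no genotypes given")
    bg <- model$b_g[genotypes]
    bg[is.na(bg)] <- 0
    eta <- eta + bg
  }
  if (length(model$b_int)) {
    bi <- model$b_int[genotypes]
    bi[is.na(bi)] <- 0
    eta <- eta + bi * mvalues
  }
  if (model$b_delta != 0) {
    if (is.null(mdelta)) stop("model has b_delta but no mdelta given")
    eta <- eta + model$b_delta * mdelta
  }
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  names(y) <- sample_ids
  y
}

#' Simulate a complete two-timepoint cohort
#'
#' Draws genotypes, paired methylation, and per-age outcomes from the
#' configured models; then applies completely-at-random missingness and the
#' nested age-10 case-control subsample (unselected subjects get all-`NA`
#' age-10 methylation rows). The full generator parameterisation, plus the
#' seed, is stored verbatim in the cohort's `truth` record. The same
#' `(config, seed)` always yields a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return a `th2_cohort` (see [as_cohort()]).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  ids <- sprintf("S%04d", seq_len(n))
  geno <- simulate_genotypes(config$maf, n, config$panel, sample_ids = ids)
  meth <- simulate_methylation(n, config$moments, config$rho, config$copula,
                               sample_ids = ids)
  m10 <- beta_to_mvalue(meth$beta10)
  m18 <- beta_to_mvalue(meth$beta18)

  draw_age <- function(model, mv) {
    mvals <- if (!is.null(model$cpg)) mv[, model$cpg] else NULL
    gt <- if (!is.null(model$snp)) unclass(geno)[, model$snp] else NULL
    md <- if (model$b_delta != 0) m18[, model$cpg] - m10[, model$cpg] else NULL
    simulate_outcomes(model, mvals, gt, mdelta = md, n = n, sample_ids = ids)
  }
  asthma10 <- draw_age(config$outcome10, m10)
  asthma18 <- draw_age(config$outcome18, m18)
  phen <- data.frame(sample_id = ids, asthma10 = asthma10, asthma18 = asthma18,
                     stringsAsFactors = FALSE, row.names = NULL)

  # completely-at-random masking
  r <- config$missing
  if (r$phenotype > 0) {
    phen$asthma10[stats::runif(n) < r$phenotype] <- NA_integer_
    phen$asthma18[stats::runif(n) < r$phenotype] <- NA_integer_
  }
  g <- unclass(geno)
  if (r$genotype > 0)
    g[matrix(stats::runif(length(g)) < r$genotype, nrow(g))] <- NA_character_
  b18 <- unclass(meth$beta18)
  b10 <- unclass(meth$beta10)
  if (r$beta > 0) {
    b18[matrix(stats::runif(length(b18)) < r$beta, nrow(b18))] <- NA_real_
    b10[matrix(stats::runif(length(b10)) < r$beta, nrow(b10))] <- NA_real_
  }

  # nested age-10 methylation subsample: drawn from subjects with observed
  # age-10 asthma status, stratified as cases/controls
  if (!is.null(config$subsample)) {
    cases <- phen$sample_id[!is.na(phen$asthma10) & phen$asthma10 == 1L]
    ctrls <- phen$sample_id[!is.na(phen$asthma10) & phen$asthma10 == 0L]
    if (length(cases) < config$subsample$cases ||
        length(ctrls) < config$subsample$controls)
      stop("requested age-10 subsample (", config$subsample$cases, " cases + ",
           config$subsample$controls, " controls) exceeds available counts (",
           length(cases), " cases, ", length(ctrls), " controls)")
    keep <- c(sample(cases, config$subsample$cases),
              sample(ctrls, config$subsample$controls))
    b10[!(ids %in% keep), ] <- NA_real_
  }

  truth <- list(
    seed = seed, n = n, maf = as.list(config$maf),
    moments = config$moments, rho = config$rho, copula = config$copula,
    outcome10 = unclass(config$outcome10), outcome18 = unclass(config$outcome18),
    missing = config$missing, subsample = config$subsample)
  as_cohort(beta_matrix(b10, "age10"), beta_matrix(b18, "age18"),
            genotype_table(g), phenotype_panel(phen), truth = truth)
}
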