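#' Paired t-test for temporal methylation change at one CpG
#'
#' Classical paired t-test on the logit scale, differences taken as
#' age10 - age18 (so a positive mean difference means higher methylation in
#' childhood). A CpG is classified `dynamic` when p < `alpha`, else
#' `stable`; the classification decides which predictor the transition
#' regression uses.
#'
#' @param m10,m18 numeric vectors of logit methylation at the two ages,
#'   aligned by subject; pairs with any missing value are dropped.
#' @param alpha classification level (default 0.05, the level used for all
#'   follow-up tests after the screen).
#' @param cpg optional probe id carried into the result.
#' @return a `cpg_dynamics` one-row data.frame: `cpg`, `n_pairs`,
#'   `mean_diff`, `t`, `df`, `p`, `classification`
#'   (`"stable"`/`"dynamic"`/`"undetermined"`), `degenerate`.
#' @export
paired_methylation_test <- function(m10, m18, alpha = 0.05, cpg = NA_character_) {
  stopifnot(length(m10) == length(m18))
  keep <- !is.na(m10) & !is.na(m18)
  d <- m10[keep] - m18[keep]
  n <- length(d)
  out <- data.frame(cpg = cpg, n_pairs = n, mean_diff = NA_real_,
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    classification = "undetermined", degenerate = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("cpg_dynamics", "data.frame")
  if (n < 2L) return(out)
  out$mean_diff <- mean(d)
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # zero-variance differences: no t statistic exists
    out$degenerate <- TRUE
    out$p <- if (out$mean_diff == 0) 1 else 0
    out$classification <- if (out$p < alpha) "dynamic" else "stable"
    return(out)
  }
  tt <- stats::t.test(m10[keep], m18[keep], paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out$classification <- if (tt$p.value < alpha) "dynamic" else "stable"
  out
}

#' Temporal dynamics of a set of CpGs in a cohort
#'
#' Runs [paired_methylation_test()] on each requested probe using the
#' cohort's paired complete cases (subjects with methylation observed at
#' both ages).
#'
#' @param cohort a `th2_cohort` with age-10 methylation present.
#' @param cpgs probe ids (default: every probe of the age-18 matrix).
#' @param alpha classification level.
#' @param epsilon clip constant for [beta_to_mvalue()].
#' @return a `cpg_dynamics` data.frame, one row per probe.
#' @export
methylation_dynamics <- function(cohort, cpgs = NULL, alpha = 0.05,
                                 epsilon = 1e-6) {
  stopifnot(inherits(cohort, "th2_cohort"))
  if (is.null(cohort$beta10)) stop("cohort has no age-10 methylation")
  if (is.null(cpgs)) cpgs <- colnames(cohort$beta18)
  m10 <- beta_to_mvalue(cohort$beta10, epsilon)
  m18 <- beta_to_mvalue(cohort$beta18, epsilon)
  out <- do.call(rbind, lapply(cpgs, function(cg)
    paired_methylation_test(m10[, cg], m18[, cg], alpha = alpha, cpg = cg)))
  rownames(out) <- NULL
  out
}

#' Label each subject's asthma trajectory
#'
#' Pure function of (asthma10, asthma18): `none` (0,0), `positive` (0,1;
#' asthma-free at 10, asthma at 18), `negative` (1,0; remission),
#' `persistent` (1,1); any missing status gives `undetermined`.
#'
#' @param phenotypes a [phenotype_panel()].
#' @return data.frame `sample_id`, `label` (factor with the five levels).
#' @export
classify_transitions <- function(phenotypes) {
  stopifnot(inherits(phenotypes, "phenotype_panel"))
  a10 <- phenotypes$asthma10
  a18 <- phenotypes$asthma18
  lab <- ifelse(is.na(a10) | is.na(a18), "undetermined",
         ifelse(a10 == 0 & a18 == 0, "none",
         ifelse(a10 == 0 & a18 == 1, "positive",
         ifelse(a10 == 1 & a18 == 0, "negative", "persistent"))))
  data.frame(sample_id = phenotypes$sample_id,
             label = factor(lab, levels = c("none", "positive", "negative",
                                            "persistent", "undetermined")),
             stringsAsFactors = FALSE)
}

#' Asthma-transition regression for one CpG x SNP pair
#'
#' Compares subjects who made the given transition against subjects with no
#' asthma at either age (persistent cases and undetermined subjects are
#' excluded). The methylation predictor depends on the CpG's temporal
#' classification: for a *dynamic* CpG it is the change in logit
#' methylation (age18 - age10, so "increase over time" has positive sign);
#' for a *stable* CpG it is the age-18 logit methylation. Genotype and its
#' interaction with the predictor are included, as in the screen.
#'
#' @param cohort a `th2_cohort`.
#' @param cpg probe id.
#' @param snp SNP id.
#' @param dynamics a `cpg_dynamics` row for `cpg` (see
#'   [methylation_dynamics()]); its `classification` must not be
#'   `"undetermined"`.
#' @param direction `"positive"` or `"negative"` transition.
#' @param epsilon clip constant for [beta_to_mvalue()].
#' @param ... passed to [fit_interaction_model()].
#' @return a `th2_fit` with extra elements `direction` and `predictor`
#'   (`"delta_m"` or `"m_age18"`).
#' @export
transition_regression <- function(cohort, cpg, snp, dynamics,
                                  direction = c("positive", "negative"),
                                  epsilon = 1e-6, ...) {
  stopifnot(inherits(cohort, "th2_cohort"))
  direction <- match.arg(direction)
  dyn <- dynamics[dynamics$cpg == cpg, , drop = FALSE]
  if (nrow(dyn) != 1L) stop("dynamics must contain exactly one row for ", cpg)
  if (dyn$classification == "undetermined")
    stop("temporal classification of ", cpg, " is undetermined")
  labs <- classify_transitions(cohort$phenotypes)
  keep <- labs$label %in% c(direction, "none")
  ids <- labs$sample_id[keep]
  y <- as.integer(labs$label[keep] == direction)
  if (!any(y == 1L)) stop("degenerate outcome: no subjects with ",
                          direction, " transition")
  m18 <- beta_to_mvalue(cohort$beta18, epsilon)[ids, cpg]
  if (dyn$classification == "dynamic") {
    if (is.null(cohort$beta10)) stop("dynamic-CpG analysis needs age-10 methylation")
    pred <- m18 - beta_to_mvalue(cohort$beta10, epsilon)[ids, cpg]
    predictor <- "delta_m"
  } else {
    pred <- m18
    predictor <- "m_age18"
  }
  g <- unclass(cohort$genotypes)[ids, snp]
  fit <- fit_interaction_model(y, pred, g,
                               spec = list(gene = NA_character_, cpg = cpg,
                                           snp = snp), ...)
  fit$direction <- direction
  fit$predictor <- predictor
  fit$classification <- dyn$classification
  fit
}
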