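#' Fit one CpG x SNP logistic interaction model
#'
#' Maximum-likelihood logistic regression of a binary outcome on logit
#' methylation, categorical genotype (indicator contrasts against a
#' reference level) and their interaction:
#' `asthma ~ meth + geno + meth:geno`. Rows with any missing value are
#' excluded first (complete-case). Genotype levels with no retained
#' observations are dropped and recorded, so a k-level fit carries exactly
#' 2k coefficients (intercept, methylation, k-1 genotype contrasts, k-1
#' interaction contrasts). Per-term two-sided Wald tests are reported.
#'
#' Quasi-complete separation is not "corrected": terms whose |estimate|
#' exceeds `est_threshold` or whose SE exceeds `se_threshold` are flagged
#' (their Wald p is ~1 anyway) but still reported.
#'
#' @param outcome 0/1 vector.
#' @param meth numeric vector of logit methylation (M-values).
#' @param geno character/factor vector of genotype categories.
#' @param reference reference genotype level; default the most frequent
#'   level among analysis rows (ties broken alphabetically).
#' @param spec optional list/row with `gene`, `cpg`, `snp` identifying the
#'   model; carried into the result.
#' @param age optional `"age10"`/`"age18"` label.
#' @param est_threshold,se_threshold separation flag thresholds on
#'   |log-OR| and SE.
#' @param maxit,tol IRLS iteration cap and deviance convergence tolerance.
#' @return a `th2_fit` with elements `terms` (data.frame: `term`,
#'   `estimate`, `se`, `p`, `separation`), `n_used`, `converged`,
#'   `reference`, `dropped_levels`, `spec`, `age`.
#' @export
fit_interaction_model <- function(outcome, meth, geno, reference = NULL,
                                  spec = NULL, age = NULL,
                                  est_threshold = 10, se_threshold = 50,
                                  maxit = 100, tol = 1e-8) {
  stopifnot(length(outcome) == length(meth), length(meth) == length(geno))
  geno <- as.character(geno)
  keep <- !is.na(outcome) & !is.na(meth) & !is.na(geno)
  y <- outcome[keep]; m <- meth[keep]; g <- geno[keep]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: constant after complete-case exclusion")
  dropped <- setdiff(unique(geno[!is.na(geno)]), unique(g))
  tab <- table(g)
  levs <- names(tab)
  if (is.null(reference)) {
    # most frequent level; alphabetical tie-break
    reference <- sort(levs[tab == max(tab)])[1]
  } else if (!reference %in% levs) {
    stop("reference level '", reference, "' has no usable observations")
  }
  gf <- stats::relevel(factor(g, levels = sort(levs)), ref = reference)
  k <- nlevels(gf)
  if (length(y) < 2L * k)
    stop("under-determined model: ", length(y), " rows for ", 2L * k,
         " parameters")
  dat <- data.frame(y = y, meth = m, geno = gf)
  # monomorphic genotype in the analysis rows: no contrasts exist and the
  # model collapses to the methylation-only fit
  form <- if (k > 1L) y ~ meth * geno else y ~ meth
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = tol, maxit = maxit)))
  est <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = names(est), estimate = unname(est),
                      se = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  hit <- match(rownames(sm), terms$term)
  terms$se[hit] <- sm[, "Std. Error"]
  terms$p[hit] <- sm[, "Pr(>|z|)"]
  # human-readable term names: geno<LEV> -> geno=<LEV>
  terms$term <- sub("^\\(Intercept\\)$", "intercept", terms$term)
  terms$term <- sub("^geno", "geno=", terms$term)
  terms$term <- sub("^meth:geno", "meth:geno=", terms$term)
  terms$separation <- !is.na(terms$estimate) &
    (abs(terms$estimate) > est_threshold |
       (!is.na(terms$se) & terms$se > se_threshold))
  structure(list(terms = terms, n_used = length(y),
                 converged = fit$converged, reference = reference,
                 dropped_levels = sort(dropped),
                 spec = spec, age = age, glm = fit),
            class = "th2_fit")
}

#' @export
print.th2_fit <- function(x, digits = 4, ...) {
  hdr <- if (!is.null(x$spec))
    paste0(x$spec$gene, ": ", x$spec$cpg, " x ", x$spec$snp) else
      "CpG x SNP interaction model"
  cat(hdr, if (!is.null(x$age)) paste0(" [", x$age, "]"), "\n", sep = "")
  cat("  n =", x$n_used, "| reference genotype:", x$reference,
      if (!x$converged) "| NOT converged", "\n")
  if (length(x$dropped_levels))
    cat("  dropped genotype level(s):", paste(x$dropped_levels, collapse = ", "), "\n")
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, digits)
  tt$se <- signif(tt$se, digits)
  tt$p <- signif(tt$p, digits)
  tt$flag <- ifelse(tt$separation, "sep", "")
  print(tt[, c("term", "estimate", "se", "p", "flag")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.th2_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$terms)
}

#' @export
coef.th2_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
vcov.th2_fit <- function(object, ...) stats::vcov(object$glm)
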