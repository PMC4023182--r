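#' Apply the candidate-model selection rule
#'
#' A fitted CpG x SNP model is selected if its methylation main effect, or
#' any single methylation-by-genotype interaction contrast, is significant
#' at `alpha` by two-sided Wald test. Separation-flagged terms are barred
#' from triggering by default (their Wald p is near 1 under separation, so
#' this rarely matters, but keeps the rule honest). An optional joint Wald
#' test over all interaction contrasts can replace the per-contrast rule.
#'
#' @param fits list of `th2_fit` objects (failed fits may appear as `NULL`
#'   or objects of class `th2_fit_failure`; they are never selected).
#' @param alpha significance level in (0, 1).
#' @param allow_separated if `TRUE`, separation-flagged terms may trigger.
#' @param joint_interaction if `TRUE`, the interaction trigger is a joint
#'   Wald chi-square test of all interaction contrasts instead of the
#'   per-contrast minimum.
#' @return data.frame with one row per fit: `gene`, `cpg`, `snp`, `age`,
#'   `selected`, `trigger` (`"methylation_main"`, `"interaction"`,
#'   `"both"` or `NA`), `p_meth`, `p_int_min`, `alpha`.
#' @export
select_models <- function(fits, alpha, allow_separated = FALSE,
                          joint_interaction = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (inherits(fits, "th2_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    base <- data.frame(gene = NA_character_, cpg = NA_character_,
                       snp = NA_character_, age = NA_character_,
                       selected = FALSE, trigger = NA_character_,
                       p_meth = NA_real_, p_int_min = NA_real_,
                       alpha = alpha, stringsAsFactors = FALSE)
    if (!inherits(f, "th2_fit")) return(base)
    if (!is.null(f$spec)) {
      base$gene <- f$spec$gene; base$cpg <- f$spec$cpg; base$snp <- f$spec$snp
    }
    if (!is.null(f$age)) base$age <- f$age
    tt <- f$terms
    usable <- !is.na(tt$p) & (allow_separated | !tt$separation)
    p_meth <- tt$p[tt$term == "meth" & usable]
    ints <- grepl("^meth:geno=", tt$term) & usable
    p_int <- if (joint_interaction) joint_wald_p(f) else
      suppressWarnings(min(tt$p[ints], na.rm = TRUE))
    if (!is.finite(p_int)) p_int <- NA_real_
    base$p_meth <- if (length(p_meth)) p_meth else NA_real_
    base$p_int_min <- p_int
    hit_m <- isTRUE(base$p_meth < alpha)
    hit_i <- isTRUE(p_int < alpha)
    base$selected <- f$converged && (hit_m || hit_i)
    if (base$selected)
      base$trigger <- if (hit_m && hit_i) "both" else
        if (hit_m) "methylation_main" else "interaction"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# joint Wald chi-square over all interaction contrasts of a th2_fit
joint_wald_p <- function(fit) {
  idx <- grep("^meth:geno", names(stats::coef(fit$glm)))
  b <- stats::coef(fit$glm)[idx]
  ok <- !is.na(b)
  if (!any(ok)) return(NA_real_)
  b <- b[ok]
  V <- stats::vcov(fit$glm)[idx[ok], idx[ok], drop = FALSE]
  w <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (is.na(w)) return(NA_real_)
  stats::pchisq(w, df = length(b), lower.tail = FALSE)
}

#' Run the CpG x SNP interaction screen over a cohort
#'
#' Enumerates every within-gene CpG x SNP pair of the panel (minus excluded
#' probes), fits the logistic interaction model at the requested age, and
#' applies the selection rule. Per-model failures (degenerate outcome,
#' under-determined design, ...) are captured, never raised. Ordering is
#' deterministic (gene, cpg, snp lexicographic).
#'
#' @param cohort a `th2_cohort`.
#' @param panel a [panel_definition()].
#' @param age `"age10"` or `"age18"`: which asthma status and methylation
#'   matrix to use.
#' @param alpha screening significance level (the two-stage design of the
#'   study uses 0.01, relaxed to 0.05 in small samples).
#' @param exclude_probes character vector of probe ids to drop (probe-SNP
#'   exclusion list).
#' @param epsilon clip constant for [beta_to_mvalue()].
#' @param ... passed to [fit_interaction_model()].
#' @return a `th2_screen`: list with `fits` (named list, `gene|cpg|snp`
#'   keys), `selection` (from [select_models()]), `failures` (data.frame of
#'   captured errors), `age`, `alpha`, `n_models`.
#' @export
run_screen <- function(cohort, panel, age = c("age18", "age10"), alpha = 0.01,
                       exclude_probes = character(), epsilon = 1e-6, ...) {
  stopifnot(inherits(cohort, "th2_cohort"))
  age <- match.arg(age)
  models <- enumerate_models(panel)
  models <- models[!models$cpg %in% exclude_probes, , drop = FALSE]
  beta <- if (age == "age10") cohort$beta10 else cohort$beta18
  if (is.null(beta)) stop("cohort has no methylation at ", age)
  mv <- beta_to_mvalue(beta, epsilon)
  y_all <- if (age == "age10") cohort$phenotypes$asthma10 else
    cohort$phenotypes$asthma18
  names(y_all) <- cohort$phenotypes$sample_id
  ids <- rownames(beta)
  y_all <- y_all[ids]
  g_all <- unclass(cohort$genotypes)[ids, , drop = FALSE]

  fits <- vector("list", nrow(models))
  fails <- list()
  for (i in seq_len(nrow(models))) {
    sp <- models[i, ]
    res <- tryCatch(
      fit_interaction_model(y_all, mv[, sp$cpg], g_all[, sp$snp],
                            spec = as.list(sp), age = age, ...),
      error = function(e) structure(list(spec = as.list(sp), age = age,
                                         message = conditionMessage(e)),
                                    class = "th2_fit_failure"))
    fits[[i]] <- res
    if (inherits(res, "th2_fit_failure"))
      fails[[length(fails) + 1L]] <- data.frame(
        gene = sp$gene, cpg = sp$cpg, snp = sp$snp, age = age,
        message = res$message, stringsAsFactors = FALSE)
  }
  names(fits) <- paste(models$gene, models$cpg, models$snp, sep = "|")
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(gene = character(), cpg = character(), snp = character(),
               age = character(), message = character(), stringsAsFactors = FALSE)
  selection <- select_models(fits, alpha)
  selection$gene <- models$gene; selection$cpg <- models$cpg
  selection$snp <- models$snp; selection$age <- age
  structure(list(fits = fits, selection = selection, failures = failures,
                 age = age, alpha = alpha, n_models = nrow(models)),
            class = "th2_screen")
}

#' @export
print.th2_screen <- function(x, ...) {
  cat("CpG x SNP interaction screen [", x$age, "], alpha = ", x$alpha, "\n",
      sep = "")
  cat("  ", x$n_models, " models fit (", nrow(x$failures), " failures), ",
      sum(x$selection$selected), " selected\n", sep = "")
  sel <- x$selection[x$selection$selected, , drop = FALSE]
  if (nrow(sel)) print(sel[, c("gene", "cpg", "snp", "trigger", "p_meth",
                               "p_int_min")], row.names = FALSE)
  invisible(x)
}

#' Long per-term results table of a screen
#'
#' One row per coefficient per successfully fitted model, mirroring the
#' layout of the published per-gene results tables (gene, cpg, snp, age,
#' term, estimate, SE, p, flags).
#'
#' @param x a `th2_screen`.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.th2_screen <- function(x, ...) {
  rows <- lapply(x$fits, function(f) {
    if (!inherits(f, "th2_fit")) return(NULL)
    data.frame(gene = f$spec$gene, cpg = f$spec$cpg, snp = f$spec$snp,
               age = f$age, reference = f$reference, f$terms,
               n_used = f$n_used, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
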