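#' Assemble a two-timepoint cohort
#'
#' Bundles the methylation matrices at both ages, the genotype table and the
#' phenotype panel under a shared set of sample ids. All analysis stages
#' (screen, bootstrap, temporal, transition) consume this container.
#'
#' @param beta10,beta18 [beta_matrix()] objects at `age10`/`age18`; `beta10`
#'   may cover only a subsample (rows of all-`NA` for unmeasured subjects).
#' @param genotypes a [genotype_table()].
#' @param phenotypes a [phenotype_panel()].
#' @param truth optional list of generator parameters (kept verbatim).
#' @return a `th2_cohort` list with elements `beta10`, `beta18`,
#'   `genotypes`, `phenotypes`, `truth`, `sample_ids`.
#' @export
as_cohort <- function(beta10, beta18, genotypes, phenotypes, truth = NULL) {
  stopifnot(inherits(beta18, "beta_matrix"), inherits(genotypes, "genotype_table"),
            inherits(phenotypes, "phenotype_panel"))
  ids <- phenotypes$sample_id
  for (tab in list(rownames(beta18), rownames(genotypes))) {
    if (!identical(sort(tab), sort(ids)))
      stop("all cohort tables must share the same sample ids")
  }
  if (!is.null(beta10)) {
    stopifnot(inherits(beta10, "beta_matrix"))
    if (!identical(sort(rownames(beta10)), sort(ids)))
      stop("all cohort tables must share the same sample ids")
    beta10 <- beta10[ids, , drop = FALSE]
    class(beta10) <- c("beta_matrix", "matrix", "array")
    attr(beta10, "timepoint") <- "age10"
  }
  beta18 <- beta18[ids, , drop = FALSE]
  class(beta18) <- c("beta_matrix", "matrix", "array")
  attr(beta18, "timepoint") <- "age18"
  genotypes <- genotypes[ids, , drop = FALSE]
  class(genotypes) <- c("genotype_table", "matrix", "array")
  structure(list(beta10 = beta10, beta18 = beta18, genotypes = genotypes,
                 phenotypes = phenotypes, truth = truth, sample_ids = ids),
            class = "th2_cohort")
}

#' @export
print.th2_cohort <- function(x, ...) {
  cat("Two-timepoint cohort:", length(x$sample_ids), "samples\n")
  n10 <- if (is.null(x$beta10)) 0L else sum(stats::complete.cases(unclass(x$beta10)))
  cat("  methylation: ", ncol(x$beta18), " CpGs (age 18: ", nrow(x$beta18),
      " samples; age 10 complete rows: ", n10, ")\n", sep = "")
  cat("  genotypes:   ", ncol(x$genotypes), " SNPs\n", sep = "")
  cat("  asthma:      age10 ", sum(x$phenotypes$asthma10, na.rm = TRUE),
      " cases / age18 ", sum(x$phenotypes$asthma18, na.rm = TRUE),
      " cases\n", sep = "")
  if (!is.null(x$truth)) cat("  simulated cohort (truth record attached)\n")
  invisible(x)
}

# Row-resample a cohort by sample id (bootstrap unit = subject). Duplicated
# draws get fresh unique ids so downstream tables keep unique rownames.
resample_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "th2_cohort"))
  new_ids <- make.unique(ids, sep = "#")
  take <- match(ids, cohort$sample_ids)
  if (anyNA(take)) stop("unknown sample id(s) in resample")
  reclass <- function(m, cls, tp = NULL) {
    out <- m[take, , drop = FALSE]
    rownames(out) <- new_ids
    class(out) <- c(cls, "matrix", "array")
    if (!is.null(tp)) attr(out, "timepoint") <- tp
    out
  }
  b10 <- if (is.null(cohort$beta10)) NULL else
    reclass(unclass(cohort$beta10), "beta_matrix", "age10")
  b18 <- reclass(unclass(cohort$beta18), "beta_matrix", "age18")
  g <- reclass(unclass(cohort$genotypes), "genotype_table")
  ph <- cohort$phenotypes[take, , drop = FALSE]
  ph$sample_id <- new_ids
  rownames(ph) <- NULL
  class(ph) <- c("phenotype_panel", "data.frame")
  as_cohort(b10, b18, g, ph, truth = cohort$truth)
}

#' Write all cohort tables to a directory
#'
#' Emits `beta_age10.tsv`, `beta_age18.tsv`, `genotypes.tsv`,
#' `phenotypes.tsv` and, for simulated cohorts, `truth.json` (the generator
#' parameters exactly as used).
#'
#' @param cohort a `th2_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "th2_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$beta10))
    write_beta_matrix(cohort$beta10, file.path(dir, "beta_age10.tsv"))
  write_beta_matrix(cohort$beta18, file.path(dir, "beta_age18.tsv"))
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort TSVs.
#' @param panel optional [panel_definition()] for genotype validation.
#' @return a `th2_cohort`.
#' @export
read_cohort <- function(dir, panel = NULL) {
  b10p <- file.path(dir, "beta_age10.tsv")
  b10 <- if (file.exists(b10p)) read_beta_matrix(b10p, "age10") else NULL
  b18 <- read_beta_matrix(file.path(dir, "beta_age18.tsv"), "age18")
  g <- read_genotypes(file.path(dir, "genotypes.tsv"), panel)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  tp <- file.path(dir, "truth.json")
  truth <- if (file.exists(tp)) jsonlite::fromJSON(tp, simplifyVector = TRUE) else NULL
  as_cohort(b10, b18, g, ph, truth = truth)
}
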