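#' Draw one bootstrap resample of sample ids
#'
#' Uniform draw with replacement, size equal to the original sample. The
#' resampling unit is the subject: downstream, a drawn id carries its whole
#' row (methylation at both ages, genotypes, phenotype) jointly.
#'
#' @param sample_ids character vector of ids.
#' @param seed optional; when given, seeds the RNG first.
#' @return character vector (multiset) of the same length.
#' @export
draw_bootstrap_indices <- function(sample_ids, seed = NULL) {
  if (!length(sample_ids)) stop("cannot resample an empty id list")
  if (!is.null(seed)) set.seed(seed)
  sample(sample_ids, length(sample_ids), replace = TRUE)
}

#' Bootstrap selection frequencies for the interaction screen
#'
#' Repeats the full screen on `B` subject-level bootstrap resamples of the
#' cohort and counts, per CpG x SNP model, how often it satisfies the
#' selection rule. Per-replicate seeds are derived deterministically from
#' the master seed (`seed + b`), so runs are bit-reproducible and
#' individual replicates can be regenerated in isolation. Failed or
#' non-converged fits in a replicate count as "not selected", keeping
#' counts in \[0, B\].
#'
#' @param cohort a `th2_cohort`.
#' @param panel a [panel_definition()].
#' @param age `"age10"` or `"age18"`.
#' @param alpha selection level applied inside every replicate (the study's
#'   two-stage convention: 0.05 for the small age-10 sample, 0.01 at 18).
#' @param B number of bootstrap samples (1,000 in the full design; scale
#'   down for desk runs).
#' @param seed integer master seed.
#' @param threshold retention threshold on counts; a model passes if
#'   `count > threshold` (strict, default `B/2` from the ">500 of 1,000"
#'   retention rule).
#' @param exclude_probes passed to [run_screen()].
#' @param original_indices if `TRUE`, skip resampling and run every
#'   replicate on the original cohort (degenerate consistency mode).
#' @param ... passed on to [run_screen()].
#' @return a `th2_boot`: list with `summaries` (data.frame: `gene`, `cpg`,
#'   `snp`, `age`, `count`, `B`, `frequency`, `rank`, `passes_threshold`),
#'   `age`, `alpha`, `B`, `seed`, `threshold`.
#' @export
bootstrap_frequencies <- function(cohort, panel, age = c("age18", "age10"),
                                  alpha = 0.01, B = 1000, seed = 1L,
                                  threshold = B / 2,
                                  exclude_probes = character(),
                                  original_indices = FALSE, ...) {
  stopifnot(B >= 1)
  age <- match.arg(age)
  models <- enumerate_models(panel)
  models <- models[!models$cpg %in% exclude_probes, , drop = FALSE]
  counts <- integer(nrow(models))
  for (b in seq_len(B)) {
    boot <- if (original_indices) cohort else {
      ids <- draw_bootstrap_indices(cohort$sample_ids,
                                    seed = (seed + b) %% .Machine$integer.max)
      resample_cohort(cohort, ids)
    }
    scr <- run_screen(boot, panel, age = age, alpha = alpha,
                      exclude_probes = exclude_probes, ...)
    counts <- counts + as.integer(scr$selection$selected)
  }
  summaries <- data.frame(models, age = age, count = counts, B = as.integer(B),
                          frequency = counts / B, stringsAsFactors = FALSE)
  summaries <- rank_models(summaries, threshold = threshold)
  structure(list(summaries = summaries, age = age, alpha = alpha,
                 B = as.integer(B), seed = seed, threshold = threshold),
            class = "th2_boot")
}

#' Rank bootstrap summaries by selection frequency
#'
#' Descending by count; ties broken lexicographically by (gene, cpg, snp).
#' A model passes the retention threshold only with `count > threshold`
#' (strictly greater).
#'
#' @param summaries data.frame with columns `gene`, `cpg`, `snp`, `count`,
#'   `B` (all rows must share one `B`).
#' @param threshold retention count threshold (default `B/2`).
#' @return the data.frame, sorted, with `rank` (1-based) and
#'   `passes_threshold` columns.
#' @export
rank_models <- function(summaries, threshold = NULL) {
  if (length(unique(summaries$B)) != 1L)
    stop("summaries mix different numbers of bootstrap samples B")
  if (is.null(threshold)) threshold <- summaries$B[1] / 2
  o <- order(-summaries$count, summaries$gene, summaries$cpg, summaries$snp)
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$passes_threshold <- out$count > threshold
  rownames(out) <- NULL
  out
}

#' @export
print.th2_boot <- function(x, n = 10, ...) {
  cat("Bootstrap model validation [", x$age, "]: B = ", x$B,
      ", alpha = ", x$alpha, ", retention count > ", x$threshold, "\n", sep = "")
  top <- utils::head(x$summaries, n)
  print(top[, c("rank", "gene", "cpg", "snp", "count", "B",
                "passes_threshold")], row.names = FALSE)
  if (nrow(x$summaries) > n) cat("  ... ", nrow(x$summaries) - n,
                                 " more models\n", sep = "")
  invisible(x)
}
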