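#' Chi-square comparison of two proportions (2x2 table)
#'
#' Pearson chi-square with 1 df on a group x trait 2x2 count table, as used
#' for subsample-vs-cohort representativeness checks. Continuity correction
#' is off by default.
#'
#' @param table 2x2 numeric matrix of non-negative counts, or the four
#'   counts `c(a, b, c, d)` filled row-wise.
#' @param correction apply Yates continuity correction.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' # asthma at 18, full cohort vs methylation subsample
#' compare_proportions(matrix(c(128, 531, 35, 210), 2, byrow = TRUE))
#' @export
compare_proportions <- function(table, correction = FALSE) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(table) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("undefined test: table total is zero")
  res <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Compares two group means given only (mean, SD, n) per group, as needed
#' when one side is published summary data. Welch's unequal-variance test
#' by default; pooled-variance optional.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param pooled use the pooled-variance (equal variance) test.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' compare_means(10, 2, 16, 12, 2, 16, pooled = TRUE)  # t = -2.83, p = 0.0083
#' @export
compare_means <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) {
    # degenerate: no within-group variability
    if (mean1 == mean2) return(list(statistic = 0, df = n1 + n2 - 2, p.value = 1))
    return(list(statistic = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2,
                p.value = 0))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Representativeness comparison of a subsample against its cohort
#'
#' Builds the standard characteristics table: chi-square tests on Yes/No
#' traits and two-sample t-tests on continuous traits, comparing a
#' subsample with the full cohort. Overlap between the two groups is
#' ignored (the nested subsample is tested against the full cohort as if
#' independent), replicating the published convention.
#'
#' @param categorical data.frame with columns `factor`, `cohort_yes`,
#'   `cohort_no`, `sub_yes`, `sub_no` (counts), or `NULL`.
#' @param continuous data.frame with columns `factor`, `cohort_mean`,
#'   `cohort_sd`, `cohort_n`, `sub_mean`, `sub_sd`, `sub_n`, or `NULL`.
#' @param correction continuity correction for the chi-square rows.
#' @param pooled pooled-variance t for the continuous rows.
#' @return data.frame with `factor`, `type`, `statistic`, `p.value`.
#' @export
compare_groups_table <- function(categorical = NULL, continuous = NULL,
                                 correction = FALSE, pooled = FALSE) {
  rows <- list()
  if (!is.null(categorical)) for (i in seq_len(nrow(categorical))) {
    r <- categorical[i, ]
    res <- compare_proportions(matrix(c(r$cohort_yes, r$cohort_no,
                                        r$sub_yes, r$sub_no), 2, byrow = TRUE),
                               correction = correction)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = r$factor, type = "chi-square",
      statistic = res$statistic, p.value = res$p.value,
      stringsAsFactors = FALSE)
  }
  if (!is.null(continuous)) for (i in seq_len(nrow(continuous))) {
    r <- continuous[i, ]
    res <- compare_means(r$cohort_mean, r$cohort_sd, r$cohort_n,
                         r$sub_mean, r$sub_sd, r$sub_n, pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = r$factor, type = "t-test",
      statistic = res$statistic, p.value = res$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
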