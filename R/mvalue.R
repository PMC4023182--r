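#' Logit (M-value) transform of methylation beta values
#'
#' All regressions and t-tests in the pipeline run on the logit scale:
#' M = log(beta / (1 - beta)). Betas are first clamped to
#' \[epsilon, 1 - epsilon\] so boundary values 0/1 map to finite M-values;
#' missing values propagate.
#'
#' @param beta a [beta_matrix()] or a numeric vector/matrix of proportions.
#' @param epsilon clip constant in (0, 0.5); default `1e-6`.
#' @return same shape as `beta`, logit-transformed; for a `beta_matrix`
#'   input the result is an `mvalue_matrix` carrying the same `timepoint`.
#' @examples
#' beta_to_mvalue(0.5)   # 0
#' beta_to_mvalue(0.88)  # log(0.88/0.12) = 1.9924
#' @export
beta_to_mvalue <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be a single value in (0, 0.5)")
  vals <- unclass(beta)
  if (!all(is.na(vals)) &&
      (min(vals, na.rm = TRUE) < 0 || max(vals, na.rm = TRUE) > 1))
    stop("beta values must lie in [0, 1]")
  clamped <- pmin(pmax(vals, epsilon), 1 - epsilon)
  m <- stats::qlogis(clamped)
  if (inherits(beta, "beta_matrix")) {
    attributes(m) <- attributes(vals)
    m <- structure(m, timepoint = attr(beta, "timepoint"),
                   class = c("mvalue_matrix", "matrix", "array"))
  } else if (is.matrix(vals)) {
    dimnames(m) <- dimnames(vals)
    dim(m) <- dim(vals)
  }
  m
}

#' @export
print.mvalue_matrix <- function(x, ...) {
  cat("M-value matrix (", attr(x, "timepoint"), "): ",
      nrow(x), " samples x ", ncol(x), " CpGs\n", sep = "")
  invisible(x)
}

#' Inverse of the M-value transform
#'
#' @param m numeric vector/matrix of M-values.
#' @return methylation proportions `plogis(m)`.
#' @export
mvalue_to_beta <- function(m) stats::plogis(unclass(m))
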