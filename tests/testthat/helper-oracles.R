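# Independent oracles used to verify the package's model fits and tests.
# These deliberately share no code with the implementation.

# Plain iteratively-reweighted least squares for logistic regression.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  V <- solve(t(X * (mu * (1 - mu))) %*% X)
  list(coef = beta, se = sqrt(diag(V)))
}

# Pearson chi-square on a 2x2 via the closed form N(ad-bc)^2/(r1 r2 c1 c2).
chisq_closed <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Paired t from the textbook closed form dbar / (s_d / sqrt(n)), df = n - 1.
paired_t_closed <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Minimal one-gene panel for small fixtures.
tiny_panel <- function(n_cpgs = 1, n_snps = 1, gene = "G1") {
  panel_definition(
    cpgs = data.frame(gene = gene,
                      probe = sprintf("cg%s%03d", gene, seq_len(n_cpgs)),
                      chrom = "1", pos = 1000L + seq_len(n_cpgs),
                      region = "Body", stringsAsFactors = FALSE),
    snps = data.frame(gene = gene,
                      snp = sprintf("rs%s%03d", gene, seq_len(n_snps)),
                      allele1 = "A", allele2 = "G", stringsAsFactors = FALSE))
}

# Panel of many independent single-pair genes (null-simulation layouts).
pairs_panel <- function(n_pairs) {
  genes <- sprintf("g%04d", seq_len(n_pairs))
  panel_definition(
    cpgs = data.frame(gene = genes, probe = sprintf("cgP%06d", seq_len(n_pairs)),
                      chrom = "1", pos = 1000L + seq_len(n_pairs),
                      region = "Body", stringsAsFactors = FALSE),
    snps = data.frame(gene = genes, snp = sprintf("rsP%06d", seq_len(n_pairs)),
                      allele1 = "A", allele2 = "G", stringsAsFactors = FALSE))
}

# Flat per-CpG beta moments table for a panel.
flat_moments <- function(panel, mean10 = 0.5, sd10 = 0.1,
                         mean18 = mean10, sd18 = sd10) {
  data.frame(probe = panel$cpgs$probe, mean10 = mean10, sd10 = sd10,
             mean18 = mean18, sd18 = sd18, stringsAsFactors = FALSE)
}

flat_mafs <- function(panel, maf = 0.3) {
  setNames(rep(maf, nrow(panel$snps)), panel$snps$snp)
}
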