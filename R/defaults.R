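#' Built-in Th2 pathway gene panel
#'
#' The five-gene Th2 cytokine panel used throughout the package examples:
#' IL4 (5 CpGs / 4 SNPs), IL4R (10 / 13), IL13 (9 / 7), GATA3 (67 / 17) and
#' STAT6 (9 / 1) -- 100 CpGs and 42 SNPs in total, giving a within-gene
#' CpG x SNP model space of 1,361 models (1,139 of them in GATA3).
#'
#' Probe and SNP identifiers with published coordinates/genotype categories
#' exist only for a handful of sites (cg23943829, cg09791102, cg26937798,
#' cg12405139, cg13543854 and nine rs ids); the remaining identifiers are
#' synthetic placeholders (prefixes `cg9xx`/`rs99x`) with deterministic
#' plausible positions, present so that the panel reaches the stated
#' per-gene totals.
#'
#' @return a [panel_definition()].
#' @export
th2_panel <- function() {
  known_cpgs <- data.frame(
    gene   = c("GATA3", "GATA3", "IL4R", "IL4R", "IL4"),
    probe  = c("cg12405139", "cg13543854", "cg09791102", "cg26937798", "cg23943829"),
    chrom  = c("10", "10", "16", "16", "5"),
    pos    = c(8106035L, 8095477L, 27353414L, 27326054L, 13200911L),
    region = c("Body", "TSS200;TSS1500", "Body", "5'UTR", "TSS1500"),
    stringsAsFactors = FALSE)

  known_snps <- data.frame(
    gene    = c("GATA3", "GATA3", "IL4R", "IL4R", "IL4R", "IL4R", "IL4R",
                "IL4", "IL4"),
    snp     = c("rs568727", "rs2229359", "rs8832", "rs1110470", "rs1805011",
                "rs1805012", "rs3024685", "rs2070874", "rs2243250"),
    allele1 = c("A", "A", "A", "A", "C", "G", "G", "A", "A"),
    allele2 = c("C", "G", "G", "G", "A", "A", "A", "G", "G"),
    stringsAsFactors = FALSE)

  totals <- data.frame(
    gene   = c("IL4", "IL4R", "IL13", "GATA3", "STAT6"),
    n_cpgs = c(5L, 10L, 9L, 67L, 9L),
    n_snps = c(4L, 13L, 7L, 17L, 1L),
    chrom  = c("5", "16", "5", "10", "12"),
    anchor = c(13200911L, 27326054L, 131992000L, 8095477L, 57489000L),
    stringsAsFactors = FALSE)

  regions <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")
  cpg_blocks <- list(known_cpgs)
  snp_blocks <- list(known_snps)
  cg_counter <- 0L
  rs_counter <- 0L
  for (i in seq_len(nrow(totals))) {
    g <- totals$gene[i]
    extra_c <- totals$n_cpgs[i] - sum(known_cpgs$gene == g)
    if (extra_c > 0L) {
      idx <- cg_counter + seq_len(extra_c)
      cg_counter <- cg_counter + extra_c
      cpg_blocks[[length(cpg_blocks) + 1L]] <- data.frame(
        gene = g,
        probe = sprintf("cg9%07d", idx),
        chrom = totals$chrom[i],
        pos = totals$anchor[i] + 500L * seq_len(extra_c),
        region = regions[(idx - 1L) %% length(regions) + 1L],
        stringsAsFactors = FALSE)
    }
    extra_s <- totals$n_snps[i] - sum(known_snps$gene == g)
    if (extra_s > 0L) {
      idx <- rs_counter + seq_len(extra_s)
      rs_counter <- rs_counter + extra_s
      a1 <- c("A", "C", "G", "T")[(idx - 1L) %% 4L + 1L]
      a2 <- c("G", "T", "A", "C")[(idx - 1L) %% 4L + 1L]
      snp_blocks[[length(snp_blocks) + 1L]] <- data.frame(
        gene = g,
        snp = sprintf("rs99%06d", idx),
        allele1 = a1, allele2 = a2,
        stringsAsFactors = FALSE)
    }
  }
  panel_definition(do.call(rbind, cpg_blocks), do.call(rbind, snp_blocks))
}

#' Default per-CpG methylation moments for simulation
#'
#' Beta-value means and SDs at the two ages. The five CpGs with published
#' summary statistics use those values; all other (synthetic placeholder)
#' probes receive deterministic, array-realistic values: alternating low
#' (~0.05) and high (~0.85) methylation with SDs of 0.01--0.03 and a small
#' negative age drift, honouring the beta-distribution feasibility bound
#' SD^2 < mean(1-mean).
#'
#' @param panel a [panel_definition()]; defaults to [th2_panel()].
#' @return data.frame with columns `probe`, `mean10`, `sd10`, `mean18`,
#'   `sd18`, one row per panel probe in panel order.
#' @export
default_beta_moments <- function(panel = th2_panel()) {
  known <- data.frame(
    probe  = c("cg12405139", "cg13543854", "cg09791102", "cg26937798", "cg23943829"),
    mean10 = c(0.93, 0.047, 0.94, 0.076, 0.88),
    sd10   = c(0.0008, 0.007, 0.046, 0.022, 0.016),
    mean18 = c(0.92, 0.042, 0.94, 0.062, 0.86),
    sd18   = c(0.011, 0.008, 0.050, 0.013, 0.019),
    stringsAsFactors = FALSE)
  probes <- panel$cpgs$probe
  out <- data.frame(probe = probes, mean10 = NA_real_, sd10 = NA_real_,
                    mean18 = NA_real_, sd18 = NA_real_,
                    stringsAsFactors = FALSE)
  hit <- match(probes, known$probe)
  out[!is.na(hit), -1] <- known[hit[!is.na(hit)], -1]
  miss <- which(is.na(out$mean10))
  if (length(miss)) {
    j <- seq_along(miss)
    low <- j %% 2L == 1L
    m <- ifelse(low, 0.04 + 0.01 * (j %% 5L), 0.82 + 0.015 * (j %% 5L))
    s <- 0.012 + 0.004 * (j %% 4L)
    out$mean10[miss] <- m
    out$sd10[miss] <- s
    out$mean18[miss] <- pmax(0.02, m - 0.005)
    out$sd18[miss] <- s + 0.002
  }
  out
}

#' Default per-SNP minor allele frequencies for simulation
#'
#' The nine SNPs with published genotype frequencies get allele-count
#' estimates derived from those frequencies; synthetic placeholder SNPs get
#' a deterministic cycle over realistic MAFs (0.05--0.45), including rare
#' variants so that sparse genotype strata occur as they do in candidate
#' gene panels.
#'
#' @param panel a [panel_definition()]; defaults to [th2_panel()].
#' @return named numeric vector of minor allele frequencies over
#'   `panel$snps$snp`.
#' @export
default_mafs <- function(panel = th2_panel()) {
  known <- c(
    rs568727  = (2 * 26 + 95) / (2 * 213),
    rs2229359 = (2 * 2 + 30) / (2 * 234),
    rs8832    = (2 * 51 + 111) / (2 * 233),
    rs1110470 = (2 * 45 + 112) / (2 * 227),
    rs1805011 = (2 * 5 + 47) / (2 * 232),
    rs1805012 = (2 * 5 + 44) / (2 * 231),
    rs3024685 = (2 * 42 + 104) / (2 * 231),
    rs2070874 = 61 / (2 * 231),
    rs2243250 = 63 / (2 * 228))
  snps <- panel$snps$snp
  maf <- known[snps]
  names(maf) <- snps
  miss <- which(is.na(maf))
  if (length(miss)) {
    cycle <- c(0.10, 0.25, 0.40, 0.05, 0.30, 0.15, 0.45, 0.20, 0.35)
    maf[miss] <- cycle[(seq_along(miss) - 1L) %% length(cycle) + 1L]
  }
  maf
}
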