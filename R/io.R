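#' Construct a methylation beta-value matrix
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   CpG probes in columns. Values are methylation proportions in \[0, 1\];
#'   `NA` marks missing.
#' @param timepoint `"age10"` or `"age18"`.
#' @return a `beta_matrix`: the numeric matrix with a `timepoint` attribute.
#' @export
beta_matrix <- function(values, timepoint = c("age10", "age18")) {
  timepoint <- match.arg(timepoint)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs sample ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in beta matrix")
  rng <- range(values, na.rm = TRUE)
  if (!all(is.na(values)) && (rng[1] < 0 || rng[2] > 1))
    stop("beta values must lie in [0, 1]; found range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  structure(values, timepoint = timepoint, class = c("beta_matrix", "matrix", "array"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta matrix (", attr(x, "timepoint"), "): ",
      nrow(x), " samples x ", ncol(x), " CpGs, ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Read a beta-value matrix from TSV
#'
#' Tab-separated, header row mandatory; first column holds sample ids,
#' remaining columns one CpG probe each; `NA` is the missing marker.
#'
#' @param path TSV path.
#' @param timepoint `"age10"` or `"age18"`.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, timepoint = c("age10", "age18")) {
  timepoint <- match.arg(timepoint)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta TSV needs a sample id column plus probes: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  beta_matrix(m, timepoint)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with 17 significant digits so a write/read cycle is
#' content-identical (bit-preserving for doubles).
#'
#' @param x a [beta_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  chr <- matrix(sprintf("%.17g", unclass(x)), nrow(x),
                dimnames = dimnames(unclass(x)))
  chr[is.na(unclass(x))] <- "NA"
  df <- data.frame(sample_id = rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype table
#'
#' Genotypes are unordered categories: two-character strings with alleles in
#' alphabetical order (`"AG"`, never `"GA"`); `NA` marks missing. No dosage
#' or additive coding is ever applied downstream -- genotype enters models
#' as a factor.
#'
#' @param values character matrix, samples in rows, SNPs in columns.
#' @param panel optional [panel_definition()]; when given, observed
#'   categories are validated against each SNP's allele pair.
#' @return a `genotype_table`: the character matrix, classed.
#' @export
genotype_table <- function(values, panel = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("genotype table needs sample ids as rownames and SNP ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in genotype table")
  obs <- values[!is.na(values)]
  if (length(obs) && any(nchar(obs) != 2L))
    stop("genotypes must be two-character allele strings, e.g. \"AG\"")
  # normalise allele order within the genotype string
  norm <- vapply(values, function(g) {
    if (is.na(g)) NA_character_
    else paste0(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1))
  values[] <- norm
  if (!is.null(panel)) {
    for (j in colnames(values)) {
      k <- match(j, panel$snps$snp)
      if (is.na(k)) next
      valid <- genotype_categories(panel$snps$allele1[k], panel$snps$allele2[k])
      valid <- vapply(strsplit(valid, ""), function(a)
        paste0(sort(a), collapse = ""), character(1))
      bad <- setdiff(unique(values[, j][!is.na(values[, j])]), valid)
      if (length(bad))
        stop("unknown genotype(s) for ", j, ": ", paste(bad, collapse = ", "))
    }
  }
  structure(values, class = c("genotype_table", "matrix", "array"))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", nrow(x), " samples x ", ncol(x), " SNPs, ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Read a genotype table from TSV
#'
#' Same dialect as [read_beta_matrix()]: header row, first column sample
#' ids, `NA` missing marker, genotypes as two-character allele strings.
#'
#' @param path TSV path.
#' @param panel optional [panel_definition()] for category validation.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, panel = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (ncol(df) < 2L) stop("genotype TSV needs a sample id column plus SNPs: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  genotype_table(m, panel)
}

#' Write a genotype table to TSV
#' @param x a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Diploid GT fields are collapsed to unordered two-allele categories
#' (`0/1` with REF A, ALT G becomes `"AG"`); phased and unphased calls are
#' treated alike; missing calls (`./.`) become `NA`. Requires the vcfR
#' package. Sample ids come from the VCF header, SNP ids from the ID column.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param panel optional [panel_definition()] for category validation.
#' @return a [genotype_table()].
#' @export
read_genotypes_vcf <- function(path, panel = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  out <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  for (i in seq_len(nrow(gt))) {
    all_i <- c(alleles[i, 1], strsplit(alleles[i, 2], ",")[[1]])
    calls <- gt[i, ]
    parsed <- vapply(calls, function(g) {
      if (is.na(g)) return(NA_character_)
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (length(idx) != 2L || anyNA(idx)) return(NA_character_)
      paste0(sort(all_i[idx + 1L]), collapse = "")
    }, character(1))
    out[, i] <- parsed
  }
  genotype_table(out, panel)
}

#' Construct a phenotype panel
#'
#' One row per sample with binary asthma status at ages 10 and 18 plus
#' optional covariates (atopy/eczema/rhinitis as 0/1; log10 IgE and age of
#' asthma onset as reals).
#'
#' @param df data.frame with columns `sample_id`, `asthma10`, `asthma18`
#'   and optionally more.
#' @return a `phenotype_panel` (classed data.frame).
#' @export
phenotype_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "asthma10", "asthma18")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype table")
  for (col in intersect(c("asthma10", "asthma18", "atopy", "eczema", "rhinitis"),
                        names(df))) {
    v <- df[[col]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("column '", col, "' must be 0/1/NA")
    df[[col]] <- as.integer(v)
  }
  class(df) <- c("phenotype_panel", "data.frame")
  df
}

#' Read a phenotype table from TSV
#' @param path TSV path (header row; `NA` missing marker).
#' @return a [phenotype_panel()].
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  phenotype_panel(df)
}

#' Write a phenotype table to TSV
#' @param x a [phenotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
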