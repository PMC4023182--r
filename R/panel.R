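#' Construct a validated gene-panel definition
#'
#' A panel maps each candidate gene to its methylation array probes (CpG
#' sites) and its genotyped SNPs. The CpG x SNP model space of the screen is
#' the union over genes of all within-gene probe/SNP pairs.
#'
#' @param cpgs data.frame with columns `gene`, `probe`, `chrom`, `pos`
#'   (1-based map position, Illumina MapInfo convention), `region`
#'   (annotation such as `"TSS200"`, `"Body"`, `"5'UTR"`).
#' @param snps data.frame with columns `gene`, `snp`, `allele1`, `allele2`.
#'   `allele1` is taken as the minor allele for simulation purposes.
#' @return An object of class `panel_definition`: a list with elements
#'   `cpgs` and `snps` as validated data.frames.
#' @examples
#' p <- panel_definition(
#'   cpgs = data.frame(gene = "IL4", probe = "cg23943829", chrom = "5",
#'                     pos = 13200911L, region = "TSS1500"),
#'   snps = data.frame(gene = "IL4", snp = "rs2243250",
#'                     allele1 = "A", allele2 = "G"))
#' panel_counts(p)
#' @export
panel_definition <- function(cpgs, snps) {
  cpgs <- as.data.frame(cpgs, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need_c <- c("gene", "probe", "chrom", "pos", "region")
  need_s <- c("gene", "snp", "allele1", "allele2")
  if (!all(need_c %in% names(cpgs)))
    stop("panel CpG table must have columns: ", paste(need_c, collapse = ", "))
  if (!all(need_s %in% names(snps)))
    stop("panel SNP table must have columns: ", paste(need_s, collapse = ", "))
  cpgs <- cpgs[need_c]
  snps <- snps[need_s]
  cpgs$pos <- as.integer(cpgs$pos)
  if (nrow(cpgs) == 0L || nrow(snps) == 0L)
    stop("panel must contain at least one CpG and one SNP")
  if (anyDuplicated(cpgs$probe))
    stop("duplicate probe id(s) in panel: ",
         paste(unique(cpgs$probe[duplicated(cpgs$probe)]), collapse = ", "))
  if (anyDuplicated(snps$snp))
    stop("duplicate SNP id(s) in panel: ",
         paste(unique(snps$snp[duplicated(snps$snp)]), collapse = ", "))
  if (any(is.na(cpgs$pos)) || any(cpgs$pos < 1L))
    stop("CpG map positions must be positive 1-based integers")
  genes <- union(cpgs$gene, snps$gene)
  no_cpg <- setdiff(genes, cpgs$gene)
  no_snp <- setdiff(genes, snps$gene)
  if (length(no_cpg) || length(no_snp))
    stop("every panel gene needs at least one CpG and one SNP; offending gene(s): ",
         paste(union(no_cpg, no_snp), collapse = ", "))
  bad <- nchar(snps$allele1) != 1L | nchar(snps$allele2) != 1L |
    snps$allele1 == snps$allele2
  if (any(bad))
    stop("SNP alleles must be two distinct single characters: ",
         paste(snps$snp[bad], collapse = ", "))
  structure(list(cpgs = cpgs, snps = snps), class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cnt <- panel_counts(x)
  cat("Gene panel:", nrow(cnt), "gene(s),",
      sum(cnt$n_cpgs), "CpGs,", sum(cnt$n_snps), "SNPs,",
      sum(cnt$n_models), "candidate models\n")
  print(cnt, row.names = FALSE)
  invisible(x)
}

#' Per-gene CpG, SNP and model counts of a panel
#'
#' @param panel a [panel_definition()].
#' @return data.frame with columns `gene`, `n_cpgs`, `n_snps`, `n_models`
#'   (`n_cpgs * n_snps`), one row per gene in alphabetical order.
#' @export
panel_counts <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  genes <- sort(union(panel$cpgs$gene, panel$snps$gene))
  nc <- vapply(genes, function(g) sum(panel$cpgs$gene == g), integer(1))
  ns <- vapply(genes, function(g) sum(panel$snps$gene == g), integer(1))
  data.frame(gene = genes, n_cpgs = nc, n_snps = ns, n_models = nc * ns,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enumerate the within-gene CpG x SNP model space
#'
#' Every probe of a gene is paired with every SNP of the same gene; pairs are
#' never formed across genes. The ordering is deterministic: lexicographic in
#' (gene, probe, snp).
#'
#' @param panel a [panel_definition()].
#' @return data.frame with columns `gene`, `cpg`, `snp`, one row per model.
#' @export
enumerate_models <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  genes <- sort(union(panel$cpgs$gene, panel$snps$gene))
  blocks <- lapply(genes, function(g) {
    cp <- sort(panel$cpgs$probe[panel$cpgs$gene == g])
    sn <- sort(panel$snps$snp[panel$snps$gene == g])
    grid <- expand.grid(snp = sn, cpg = cp,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(gene = g, cpg = grid$cpg, snp = grid$snp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Read a panel definition from JSON or YAML
#'
#' The file holds a list of gene blocks:
#' \preformatted{
#' {"genes": [{"gene": "IL4",
#'             "cpgs": [{"probe": "cg...", "chrom": "5",
#'                       "pos": 13200911, "region": "TSS1500"}],
#'             "snps": [{"snp": "rs...", "alleles": ["A", "G"]}]}]}
#' }
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated [panel_definition()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported panel format (expect .json/.yaml/.yml): ", path))
  if (is.null(raw$genes)) stop("panel file has no 'genes' entry: ", path)
  cpgs <- list(); snps <- list()
  for (g in raw$genes) {
    if (is.null(g$gene)) stop("panel gene block without a 'gene' name")
    if (length(g$cpgs) == 0L || length(g$snps) == 0L)
      stop("gene block '", g$gene, "' must list at least one CpG and one SNP")
    cpgs[[length(cpgs) + 1L]] <- data.frame(
      gene = g$gene,
      probe = vapply(g$cpgs, function(x) as.character(x$probe), character(1)),
      chrom = vapply(g$cpgs, function(x) as.character(x$chrom), character(1)),
      pos = vapply(g$cpgs, function(x) as.integer(x$pos), integer(1)),
      region = vapply(g$cpgs, function(x) as.character(x$region), character(1)),
      stringsAsFactors = FALSE)
    snps[[length(snps) + 1L]] <- data.frame(
      gene = g$gene,
      snp = vapply(g$snps, function(x) as.character(x$snp), character(1)),
      allele1 = vapply(g$snps, function(x) as.character(x$alleles[[1]]), character(1)),
      allele2 = vapply(g$snps, function(x) as.character(x$alleles[[2]]), character(1)),
      stringsAsFactors = FALSE)
  }
  panel_definition(do.call(rbind, cpgs), do.call(rbind, snps))
}

#' Write a panel definition to JSON or YAML
#'
#' @param panel a [panel_definition()].
#' @param path output path; format chosen by extension as in [read_panel()].
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  genes <- sort(union(panel$cpgs$gene, panel$snps$gene))
  obj <- list(genes = lapply(genes, function(g) {
    cp <- panel$cpgs[panel$cpgs$gene == g, , drop = FALSE]
    sn <- panel$snps[panel$snps$gene == g, , drop = FALSE]
    list(gene = g,
         cpgs = lapply(seq_len(nrow(cp)), function(i)
           list(probe = cp$probe[i], chrom = cp$chrom[i],
                pos = cp$pos[i], region = cp$region[i])),
         snps = lapply(seq_len(nrow(sn)), function(i)
           list(snp = sn$snp[i], alleles = list(sn$allele1[i], sn$allele2[i]))))
  }))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else stop("unsupported panel format (expect .json/.yaml/.yml): ", path)
  invisible(path)
}

#' Genotype categories implied by a SNP's allele pair
#'
#' Unordered diploid genotypes, each written with its alleles in alphabetical
#' order (heterozygote `"AG"`, never `"GA"`).
#'
#' @param allele1,allele2 single-character alleles.
#' @return character vector of the three genotype categories, minor
#'   homozygote first when `allele1` is the minor allele.
#' @export
genotype_categories <- function(allele1, allele2) {
  het <- paste0(sort(c(allele1, allele2)), collapse = "")
  c(paste0(allele1, allele1), het, paste0(allele2, allele2))
}

#' Signed CpG-SNP base-pair distances within genes
#'
#' Report-only helper: SNP genomic coordinates are not part of a panel
#' definition, so they must be supplied by the caller. The distance is
#' `snp_pos - cpg_pos` on the same chromosome (negative when the SNP lies
#' 5' of the probe position).
#'
#' @param panel a [panel_definition()].
#' @param snp_positions named integer vector of SNP coordinates (1-based,
#'   same assembly as the panel's CpG positions).
#' @return data.frame `gene`, `cpg`, `snp`, `distance_bp` for every
#'   within-gene pair whose SNP has a supplied coordinate.
#' @export
cpg_snp_distances <- function(panel, snp_positions) {
  stopifnot(inherits(panel, "panel_definition"))
  models <- enumerate_models(panel)
  models <- models[models$snp %in% names(snp_positions), , drop = FALSE]
  cpg_pos <- stats::setNames(panel$cpgs$pos, panel$cpgs$probe)
  models$distance_bp <- as.integer(snp_positions[models$snp]) -
    as.integer(cpg_pos[models$cpg])
  rownames(models) <- NULL
  models
}
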