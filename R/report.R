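#' Render publication-style per-model effect tables
#'
#' For each requested model, produces the block layout of the published
#' per-gene results tables: a methylation main-effect row, per-genotype
#' main-effect rows, and per-genotype interaction rows, with `Ref.` marking
#' the reference level and `NA` cells for genotype levels that had no
#' usable observations (dropped strata). A bootstrap frequency column is
#' attached when summaries are supplied.
#'
#' @param screen a `th2_screen`.
#' @param panel the [panel_definition()] the screen ran on (supplies the
#'   full genotype category set per SNP, so absent strata render as NA).
#' @param boot optional `th2_boot` with matching models.
#' @param models optional data.frame (`gene`, `cpg`, `snp`) restricting and
#'   ordering the report; default: selected models of the screen.
#' @return data.frame with columns `model`, `frequency`, `gene`, `cpg`,
#'   `snp`, `parameter`, `level`, `estimate`, `p`, `flag`.
#' @export
render_report <- function(screen, panel, boot = NULL, models = NULL) {
  stopifnot(inherits(screen, "th2_screen"))
  if (is.null(models)) {
    sel <- screen$selection[screen$selection$selected, , drop = FALSE]
    models <- sel[, c("gene", "cpg", "snp")]
  }
  if (!nrow(models))
    return(data.frame(model = integer(), frequency = integer(),
                      gene = character(), cpg = character(), snp = character(),
                      parameter = character(), level = character(),
                      estimate = numeric(), p = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  blocks <- lapply(seq_len(nrow(models)), function(i) {
    key <- paste(models$gene[i], models$cpg[i], models$snp[i], sep = "|")
    fit <- screen$fits[[key]]
    freq <- NA_integer_
    if (!is.null(boot)) {
      s <- boot$summaries
      hit <- s$gene == models$gene[i] & s$cpg == models$cpg[i] &
        s$snp == models$snp[i]
      if (any(hit)) freq <- s$count[hit][1]
    }
    k <- match(models$snp[i], panel$snps$snp)
    cats <- genotype_categories(panel$snps$allele1[k], panel$snps$allele2[k])
    cats <- vapply(strsplit(cats, ""), function(a) paste0(sort(a), collapse = ""),
                   character(1))
    base <- data.frame(model = i, frequency = freq, gene = models$gene[i],
                       cpg = models$cpg[i], snp = models$snp[i],
                       stringsAsFactors = FALSE)
    if (!inherits(fit, "th2_fit")) {
      row <- cbind(base, data.frame(parameter = models$cpg[i], level = "",
                                    estimate = NA_real_, p = NA_real_,
                                    flag = "fit failed", stringsAsFactors = FALSE))
      return(row)
    }
    tt <- fit$terms
    grab <- function(term) {
      j <- match(term, tt$term)
      if (is.na(j)) c(NA_real_, NA_real_, NA) else
        c(tt$estimate[j], tt$p[j], tt$separation[j])
    }
    rows <- list()
    v <- grab("meth")
    rows[[1]] <- data.frame(parameter = models$cpg[i], level = "",
                            estimate = v[1], p = v[2],
                            flag = if (isTRUE(v[3] == 1)) "sep" else "",
                            stringsAsFactors = FALSE)
    nonref <- setdiff(cats, fit$reference)
    for (what in c("geno=", "meth:geno=")) {
      pname <- if (what == "geno=") models$snp[i] else
        paste0(models$cpg[i], "*", models$snp[i])
      for (lv in nonref) {
        v <- grab(paste0(what, lv))
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pname, level = lv, estimate = v[1], p = v[2],
          flag = if (isTRUE(v[3] == 1)) "sep" else
            if (is.na(v[1])) "NA stratum" else "",
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pname, level = fit$reference, estimate = NA_real_,
        p = NA_real_, flag = "Ref.", stringsAsFactors = FALSE)
    }
    rows_df <- do.call(rbind, rows)
    cbind(base[rep(1L, nrow(rows_df)), , drop = FALSE], rows_df,
          row.names = NULL)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Render the asthma-transition effects table
#'
#' One row per CpG with the methylation(-change) main-effect log-OR and p
#' for each transition direction, split by temporal classification,
#' mirroring the published transition table layout.
#'
#' @param fits list of `th2_fit` objects from [transition_regression()]
#'   (both directions per CpG).
#' @return data.frame with `cpg`, `snp`, `classification`,
#'   `logOR_positive`, `p_positive`, `logOR_negative`, `p_negative`.
#' @export
render_transition_table <- function(fits) {
  keys <- unique(vapply(fits, function(f) paste(f$spec$cpg, f$spec$snp, sep = "|"),
                        character(1)))
  rows <- lapply(keys, function(k) {
    sub <- Filter(function(f) paste(f$spec$cpg, f$spec$snp, sep = "|") == k, fits)
    row <- data.frame(cpg = sub[[1]]$spec$cpg, snp = sub[[1]]$spec$snp,
                      classification = sub[[1]]$classification,
                      logOR_positive = NA_real_, p_positive = NA_real_,
                      logOR_negative = NA_real_, p_negative = NA_real_,
                      stringsAsFactors = FALSE)
    for (f in sub) {
      j <- match("meth", f$terms$term)
      if (f$direction == "positive") {
        row$logOR_positive <- f$terms$estimate[j]
        row$p_positive <- f$terms$p[j]
      } else {
        row$logOR_negative <- f$terms$estimate[j]
        row$p_negative <- f$terms$p[j]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$classification, out$cpg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the config
#' echo, the master seed, package and R versions, input file checksums and
#' an ISO-8601 timestamp.
#'
#' @param path output JSON path.
#' @param config list echoed verbatim.
#' @param seed master seed.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "th2screen",
    package_version = as.character(utils::packageVersion("th2screen")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
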