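# GWAS-eSNP integration: eSNP set construction, enrichment Q-Q against the
# GWAS background, and GWAS SNP -> gene translation through the eSNP list.

#' Build the eSNP set from a scan or meta-analysis
#'
#' Every cis SNP-probeset pair with P at or below the cis FDR cutoff joins
#' the set (the eSNP list is not restricted to each probeset's best SNP);
#' gene symbols are attached via the probeset annotation.
#'
#' @param scan an `eqtl_scan` or `meta_eqtl` object.
#' @param threshold cis P cutoff, or an `fdr_threshold`; defaults to the
#'   object's own cis threshold when present.
#' @return object of class `esnp_set`: data frame `pairs` (snp_id,
#'   probeset_id, gene_symbol, p) plus `snps` (unique eSNP ids) and
#'   `genes_by_snp` (named list).
#' @export
build_esnp_set <- function(scan, threshold = NULL) {
  if (is.null(threshold)) threshold <- scan$thresholds$cis
  cutoff <- if (inherits(threshold, "fdr_threshold")) threshold$p_cutoff else threshold
  if (is.null(cutoff)) stop("no cis threshold available")
  p <- if (inherits(scan, "meta_eqtl")) scan$p_fe else scan$p
  hit <- which(!is.na(p) & scan$cis & p <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    snp_id = scan$snps$snp_id[hit[, 1]],
    probeset_id = scan$probesets$probeset_id[hit[, 2]],
    gene_symbol = toupper(scan$probesets$gene_symbol[hit[, 2]]),
    p = p[hit], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$snp_id, pairs$probeset_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, snps = unique(pairs$snp_id),
                 genes_by_snp = split(pairs$gene_symbol, pairs$snp_id),
                 cutoff = cutoff),
            class = "esnp_set")
}

#' @export
print.esnp_set <- function(x, ...) {
  cat("eSNP set:", length(x$snps), "SNPs controlling",
      length(unique(x$pairs$gene_symbol)), "genes (",
      nrow(x$pairs), "cis pairs at P <=", format(x$cutoff, digits = 3), ")\n")
  invisible(x)
}

#' GWAS enrichment Q-Q of the eSNP subset
#'
#' Compares GWAS P-values of eSNPs against all remaining GWAS SNPs with a
#' one-sided Mann-Whitney test (alternative: eSNP P-values are smaller) and
#' returns expected-vs-observed -log10 P coordinates for the eSNP subset.
#'
#' @param gwas data frame with `snp_id` and `p`.
#' @param esnp_set an `esnp_set` (or character vector of SNP ids).
#' @return list of class `qq_enrichment`: `qq` data frame (expected,
#'   observed, on the -log10 scale), `enrichment_p`, `n_esnp`, `n_other`.
#' @export
enrichment_qq <- function(gwas, esnp_set) {
  snps <- if (inherits(esnp_set, "esnp_set")) esnp_set$snps else esnp_set
  in_set <- gwas$snp_id %in% snps
  if (!any(in_set)) stop("no eSNPs found in the GWAS table")
  if (all(in_set)) stop("all GWAS SNPs are eSNPs: no comparison group")
  if (sum(in_set) < 10) stop("fewer than 10 eSNPs with GWAS P-values")
  p_in <- gwas$p[in_set]; p_out <- gwas$p[!in_set]
  wt <- wilcox.test(p_in, p_out, alternative = "less", exact = FALSE)
  obs <- sort(-log10(p_in), decreasing = TRUE)
  expd <- -log10(ppoints(length(obs)))
  structure(list(qq = data.frame(expected = expd, observed = obs),
                 enrichment_p = wt$p.value,
                 n_esnp = length(p_in), n_other = length(p_out)),
            class = "qq_enrichment")
}

#' @export
print.qq_enrichment <- function(x, ...) {
  cat("GWAS enrichment:", x$n_esnp, "eSNPs vs", x$n_other,
      "other SNPs; one-sided Mann-Whitney P =",
      format(x$enrichment_p, digits = 3), "\n")
  invisible(x)
}

#' Q-Q plot of GWAS P-values at eSNPs
#'
#' @param x a `qq_enrichment`.
#' @param ... passed to [plot()].
#' @export
plot.qq_enrichment <- function(x, ...) {
  plot(x$qq$expected, x$qq$observed,
       xlab = expression(Expected ~ -log[10](P)),
       ylab = expression(Observed ~ -log[10](P)), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Translate GWAS SNPs into genes through the eSNP list
#'
#' SNPs with GWAS P strictly below `gwas_threshold` that are eSNPs emit the
#' genes whose expression they control; the unique union is reported.
#'
#' @param gwas data frame with `snp_id` and `p`.
#' @param esnp_set an `esnp_set`.
#' @param gwas_threshold strict upper bound on the GWAS P (default 0.01).
#' @return list of class `gwas_links`: `links` data frame (snp_id, gwas_p,
#'   genes as comma list), `genes` (unique union), `n_snps`.
#' @export
link_gwas_genes <- function(gwas, esnp_set, gwas_threshold = 0.01) {
  hits <- gwas[gwas$p < gwas_threshold & gwas$snp_id %in% esnp_set$snps, ,
               drop = FALSE]
  gene_sets <- esnp_set$genes_by_snp[hits$snp_id]
  links <- data.frame(snp_id = hits$snp_id, gwas_p = hits$p,
                      genes = vapply(gene_sets, function(g)
                        paste(sort(unique(g)), collapse = ","), ""),
                      stringsAsFactors = FALSE)
  links <- links[order(links$gwas_p, links$snp_id), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links,
                 genes = sort(unique(unlist(gene_sets, use.names = FALSE))),
                 n_snps = nrow(links), threshold = gwas_threshold),
            class = "gwas_links")
}

#' @export
print.gwas_links <- function(x, ...) {
  cat(x$n_snps, "GWAS SNPs (P <", x$threshold, ") linked to",
      length(x$genes), "unique genes via the eSNP list\n")
  invisible(x)
}
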