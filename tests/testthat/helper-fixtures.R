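# Shared fixture builders; everything is generated in code at test time.

# A small, fast study configuration used across module tests.
small_cfg <- function(seed = 1, ...) {
  args <- list(n_snps = 300, n_probesets = 80, samples_per_cohort = 120,
               network_genes = 40, canonical_size = 20, n_hubs = 1,
               hub_children = 8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Hand-built eqtl_scan with known entries: 3 SNPs x 2 probesets.
# SNPs 1-2 are cis to probeset 1; SNP 3 is cis to probeset 2.
tiny_scan <- function(p = matrix(c(1e-8, 1e-5, 0.5,
                                   0.9, 0.9, 1e-6), nrow = 3)) {
  snps <- data.frame(snp_id = c("snpA", "snpB", "snpC"),
                     chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100L, 200L, 300L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  probesets <- data.frame(probeset_id = c("ps1", "ps2"),
                          gene_symbol = c("GENEA", "GENEB"),
                          chrom = c("chr1", "chr2"),
                          start = c(1000L, 1000L), end = c(2000L, 2000L),
                          strand = "+", stringsAsFactors = FALSE)
  cis <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE), nrow = 3)
  structure(list(beta = matrix(0.5, 3, 2), se = matrix(0.1, 3, 2), p = p,
                 r2 = matrix(0.2, 3, 2), n = rep(100L, 3), cis = cis,
                 snps = snps, probesets = probesets, window = 1e6),
            class = "eqtl_scan")
}

# Brute-force upper-tail hypergeometric by enumerating every overlap count.
hyper_upper_enum <- function(x, k, m, n) {
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= x])
}
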