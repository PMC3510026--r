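# Per-cohort eQTL mapping: genotype QC, robust covariate adjustment,
# exhaustive additive association scan, cis/trans classification,
# permutation FDR thresholds, and best-eSNP calls.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided P for departure from Hardy-Weinberg proportions, summing
#' the probability of all heterozygote counts (conditional on the allele
#' counts) no more probable than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative genotype count")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    nr_hom <- (rare - h) / 2
    nc_hom <- n - h - nr_hom
    lfactorial(n) - lfactorial(nr_hom) - lfactorial(h) - lfactorial(nc_hom) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Removes SNPs with call rate below `call_rate_min` or an exact
#' Hardy-Weinberg test P below `hwe_alpha` (defaults: the conventional
#' call rate < 0.9 and HWE P < 1e-6 exclusions).
#'
#' @param genotypes dosage matrix (SNPs x samples), values 0/1/2 or NA.
#' @param annotations SNP annotation data frame with `snp_id` matching
#'   `rownames(genotypes)`.
#' @param call_rate_min minimum fraction of non-missing dosages.
#' @param hwe_alpha HWE exact-test significance cutoff for exclusion.
#' @return list: `genotypes` (filtered matrix), `annotations` (filtered),
#'   `report` (n_input, n_removed_callrate, n_removed_hwe, n_kept).
#' @export
qc_genotypes <- function(genotypes, annotations, call_rate_min = 0.9,
                         hwe_alpha = 1e-6) {
  stopifnot(nrow(genotypes) == nrow(annotations))
  n <- ncol(genotypes)
  call_rate <- rowMeans(!is.na(genotypes))
  fail_cr <- call_rate < call_rate_min
  hwe_p <- rep(1, nrow(genotypes))
  for (i in which(!fail_cr)) {
    g <- genotypes[i, ]
    g <- g[!is.na(g)]
    hwe_p[i] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  fail_hwe <- !fail_cr & hwe_p < hwe_alpha
  keep <- !fail_cr & !fail_hwe
  if (!any(keep)) stop("no SNPs remain after genotype QC")
  list(genotypes = genotypes[keep, , drop = FALSE],
       annotations = annotations[keep, , drop = FALSE],
       report = list(n_input = nrow(genotypes),
                     n_removed_callrate = sum(fail_cr),
                     n_removed_hwe = sum(fail_hwe),
                     n_kept = sum(keep)))
}

# Huber M-estimation by iteratively reweighted least squares with MAD scale.
huber_fit <- function(X, y, k = 1.345, tol = 1e-8, maxit = 50L) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% b)
    s <- mad(r, center = 0)
    if (s <= .Machine$double.eps) break
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)
    sw <- sqrt(w)
    b_new <- qr.coef(qr(X * sw), y * sw)
    if (max(abs(b_new - b)) <= tol * max(1, max(abs(b)))) { b <- b_new; break }
    b <- b_new
  }
  b
}

#' Robust covariate adjustment of expression
#'
#' Per probeset, fits expression on age, sex, and two smoking indicators
#' (ex and current smoker against never) by Huber M-estimation (tuning
#' constant 1.345, IRLS with re-estimated MAD scale, tolerance 1e-8, at most
#' 50 iterations) to resist expression outliers, and returns the centered
#' residuals.
#'
#' @param expression matrix probesets x samples.
#' @param covariates data frame with `age` (numeric), `sex` (0/1), and
#'   `smoking` in never/ex/current, rows aligned to expression columns.
#' @return residual matrix with the dimensions and dimnames of `expression`,
#'   each row centered at 0.
#' @export
adjust_expression <- function(expression, covariates) {
  if (ncol(expression) != nrow(covariates))
    stop("expression columns and covariate rows must match")
  if (!is.numeric(covariates$age) || !is.numeric(covariates$sex))
    stop("age and sex covariates must be numeric")
  if (!all(covariates$smoking %in% c("never", "ex", "current")))
    stop("smoking must be one of never/ex/current")
  X <- cbind(1, covariates$age, covariates$sex,
             as.numeric(covariates$smoking == "ex"),
             as.numeric(covariates$smoking == "current"))
  res <- matrix(0, nrow(expression), ncol(expression),
                dimnames = dimnames(expression))
  const <- apply(expression, 1L, function(y) diff(range(y)) == 0)
  if (any(const))
    warning(sum(const), " constant expression row(s): residuals set to zero")
  for (i in which(!const)) {
    y <- expression[i, ]
    b <- huber_fit(X, y)
    r <- y - drop(X %*% b)
    res[i, ] <- r - mean(r)
  }
  res
}

#' Classify a SNP-probeset pair as cis or trans
#'
#' Cis if and only if the SNP lies on the probeset's chromosome within
#' `window` base pairs of the probeset interval, boundary inclusive:
#' pos in \[start - window, end + window\]. Different-chromosome pairs and
#' more distal same-chromosome pairs are trans.
#'
#' @param snp one-row SNP annotation (chrom, pos).
#' @param probeset one-row probeset annotation (chrom, start, end).
#' @param window cis window in base pairs (default 1 Mb).
#' @return "cis" or "trans".
#' @export
classify_pair <- function(snp, probeset, window = 1e6) {
  if (is.na(snp$pos) || is.na(probeset$start)) stop("missing position")
  if (snp$chrom == probeset$chrom &&
      snp$pos >= probeset$start - window &&
      snp$pos <= probeset$end + window) "cis" else "trans"
}

# cis indicator matrix (SNPs x probesets) for classify_pair applied to all
# pairs at once.
cis_mask <- function(snps, probesets, window = 1e6) {
  same_chrom <- outer(snps$chrom, probesets$chrom, `==`)
  after_lo <- outer(snps$pos, probesets$start - window, `>=`)
  before_hi <- outer(snps$pos, probesets$end + window, `<=`)
  same_chrom & after_lo & before_hi
}

#' Single-pair additive association test
#'
#' Ordinary least squares of adjusted expression on allele dosage
#' (additive 0/1/2 coding); two-sided t-test P and squared Pearson
#' correlation. Missing values are dropped pairwise.
#'
#' @param dosage numeric dosage vector.
#' @param residual adjusted expression vector of the same length.
#' @param min_samples minimum non-missing pairs.
#' @return list: beta, se, p, r2, n.
#' @export
test_association <- function(dosage, residual, min_samples = 30L) {
  ok <- !is.na(dosage) & !is.na(residual)
  g <- dosage[ok]; y <- residual[ok]
  n <- length(g)
  if (n < min_samples) stop("fewer than min_samples non-missing pairs")
  if (diff(range(g)) == 0) stop("monomorphic dosage")
  gc <- g - mean(g); yc <- y - mean(y)
  sgg <- sum(gc^2); syy <- sum(yc^2); sgy <- sum(gc * yc)
  beta <- sgy / sgg
  rss <- syy - beta * sgy
  df <- n - 2L
  se <- sqrt(max(rss, 0) / df / sgg)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * pt(-abs(tval), df)
  r2 <- if (syy > 0) min(1, sgy^2 / (sgg * syy)) else NA_real_
  list(beta = beta, se = se, p = p, r2 = r2, n = n)
}

# Vectorized association of every SNP row of G against every probeset row
# of Y (both complete); returns matrices SNPs x probesets.
fast_assoc <- function(G, Y, want_r2 = TRUE) {
  n <- ncol(G)
  Gc <- G - rowMeans(G)
  Yc <- Y - rowMeans(Y)
  sgg <- rowSums(Gc^2)
  syy <- rowSums(Yc^2)
  S <- Gc %*% t(Yc)
  beta <- S / sgg
  rss <- outer(rep(1, nrow(G)), syy) - beta * S
  df <- n - 2L
  se <- sqrt(pmax(rss, 0) / df / sgg)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  bad_g <- sgg == 0; bad_y <- syy == 0
  if (any(bad_g)) beta[bad_g, ] <- se[bad_g, ] <- p[bad_g, ] <- NA_real_
  if (any(bad_y)) beta[, bad_y] <- se[, bad_y] <- p[, bad_y] <- NA_real_
  out <- list(beta = beta, se = se, p = p, n = n)
  if (want_r2) {
    r2 <- S^2 / outer(sgg, syy)
    r2[!is.finite(r2)] <- NA_real_
    out$r2 <- pmin(r2, 1)
  }
  out
}

#' Genome-wide association scan of all SNP-probeset pairs
#'
#' Tests every SNP against every adjusted expression trait with the additive
#' OLS model of [test_association()] and tags each pair cis or trans via the
#' [classify_pair()] predicate. SNPs with missing dosages are handled by
#' pairwise-complete per-SNP fits; monomorphic SNPs and constant traits are
#' skipped (NA entries).
#'
#' @param genotypes QC'd dosage matrix (SNPs x samples).
#' @param residuals adjusted expression matrix (probesets x samples), same
#'   samples in the same order.
#' @param snps,probesets annotation data frames aligned to the matrix rows.
#' @param window cis window in base pairs.
#' @param min_samples minimum non-missing pairs per test.
#' @return object of class `eqtl_scan`: matrices beta, se, p, r2
#'   (SNPs x probesets), per-SNP sample counts `n`, logical `cis` mask, and
#'   the annotations.
#' @export
eqtl_scan <- function(genotypes, residuals, snps, probesets, window = 1e6,
                      min_samples = 30L) {
  stopifnot(nrow(genotypes) == nrow(snps),
            nrow(residuals) == nrow(probesets),
            ncol(genotypes) == ncol(residuals))
  has_na <- rowSums(is.na(genotypes)) > 0
  G0 <- genotypes
  if (any(has_na)) G0[is.na(G0)] <- 0  # placeholder; rows recomputed below
  fa <- fast_assoc(G0, residuals)
  nvec <- rep(ncol(genotypes), nrow(genotypes))
  for (i in which(has_na)) {
    ok <- !is.na(genotypes[i, ])
    if (sum(ok) < min_samples || diff(range(genotypes[i, ok])) == 0) {
      fa$beta[i, ] <- fa$se[i, ] <- fa$p[i, ] <- fa$r2[i, ] <- NA_real_
      nvec[i] <- sum(ok)
      next
    }
    sub <- fast_assoc(genotypes[i, ok, drop = FALSE],
                      residuals[, ok, drop = FALSE])
    fa$beta[i, ] <- sub$beta; fa$se[i, ] <- sub$se
    fa$p[i, ] <- sub$p; fa$r2[i, ] <- sub$r2
    nvec[i] <- sum(ok)
  }
  structure(list(beta = fa$beta, se = fa$se, p = fa$p, r2 = fa$r2,
                 n = nvec, cis = cis_mask(snps, probesets, window),
                 snps = snps, probesets = probesets, window = window),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eQTL scan:", nrow(x$p), "SNPs x", ncol(x$p), "probesets (",
      sum(x$cis), "cis pairs,", sum(!x$cis), "trans pairs ), window",
      format(x$window, big.mark = ","), "bp\n")
  invisible(x)
}

#' Flatten a scan to an association table
#'
#' @param scan an `eqtl_scan`.
#' @param p_max keep only pairs with P at or below this value (the full
#'   cross is large; 1 keeps everything).
#' @param cohort cohort label for the output column.
#' @return data frame: snp_id, probeset_id, cohort, beta, se, p, r2, n, class.
#' @export
assoc_table <- function(scan, p_max = 1, cohort = "cohort") {
  idx <- which(!is.na(scan$p) & scan$p <= p_max, arr.ind = TRUE)
  data.frame(snp_id = scan$snps$snp_id[idx[, 1]],
             probeset_id = scan$probesets$probeset_id[idx[, 2]],
             cohort = cohort,
             beta = scan$beta[idx], se = scan$se[idx], p = scan$p[idx],
             r2 = scan$r2[idx], n = scan$n[idx[, 1]],
             class = ifelse(scan$cis[idx], "cis", "trans"),
             stringsAsFactors = FALSE)
}

#' Permutation-based FDR threshold
#'
#' Estimates FDR(t) = (mean permuted count at or below t) / (observed count
#' at or below t) at every observed P-value and returns the largest observed
#' P with estimated FDR at or below the target. If no threshold attains the
#' target, the cutoff is 0 with zero discoveries (with a warning).
#'
#' @param observed_p observed P-values (one class: cis or trans).
#' @param perm_p list of same-length P-value vectors from scans of
#'   label-permuted data.
#' @param target_fdr target false discovery rate (default 0.10).
#' @return list of class `fdr_threshold`: p_cutoff, n_discoveries,
#'   fdr_at_cutoff, n_permutations, target_fdr.
#' @export
estimate_fdr_threshold <- function(observed_p, perm_p, target_fdr = 0.10) {
  if (!is.list(perm_p) || length(perm_p) < 1)
    stop("at least one permutation P-value vector is required")
  obs <- sort(observed_p[!is.na(observed_p)])
  perm <- sort(unlist(perm_p, use.names = FALSE))
  perm <- perm[!is.na(perm)]
  R <- length(perm_p)
  n_obs <- seq_along(obs)
  n_perm <- findInterval(obs, perm) / R
  fdr <- n_perm / n_obs
  ok <- which(fdr <= target_fdr)
  if (length(ok) == 0) {
    warning("no threshold attains the target FDR; cutoff set to 0")
    cutoff <- 0; ndisc <- 0L; fdr_at <- NA_real_
  } else {
    i <- max(ok)
    cutoff <- obs[i]; ndisc <- i; fdr_at <- fdr[i]
  }
  structure(list(p_cutoff = cutoff, n_discoveries = ndisc,
                 fdr_at_cutoff = fdr_at, n_permutations = R,
                 target_fdr = target_fdr),
            class = "fdr_threshold")
}

# Order candidate rows by (p, pos, snp_id) and return the first: the
# best-eSNP rule with a deterministic tie-break.
best_snp <- function(p, pos, snp_id) {
  order(p, pos, snp_id)[1L]
}

#' Declare cis- and trans-eQTLs from a scan
#'
#' Cis: per probeset, the lowest-P SNP inside the cis window, if its P is at
#' or below the cis cutoff (at most one cis-eQTL per transcript). Trans: per
#' probeset and SNP chromosome, the lowest-P distal SNP at or below the trans
#' cutoff. P ties break by genomic position, then SNP id.
#'
#' @param scan an `eqtl_scan`.
#' @param thresholds list with elements `cis` and `trans`, each an
#'   `fdr_threshold` (or a bare cutoff number).
#' @param cohort cohort label.
#' @return data frame of class `eqtl_calls`: probeset_id, snp_id, class, p,
#'   beta, r2, cohort, fdr_level.
#' @export
call_eqtls <- function(scan, thresholds, cohort = "cohort") {
  if (!is.character(cohort) || length(cohort) != 1L || is.na(cohort))
    stop("cohort must be a single label")
  cutoff_of <- function(th) if (inherits(th, "fdr_threshold")) th$p_cutoff else th
  target_of <- function(th) if (inherits(th, "fdr_threshold")) th$target_fdr else NA_real_
  cis_cut <- cutoff_of(thresholds$cis)
  trans_cut <- cutoff_of(thresholds$trans)
  rows <- list()
  p <- scan$p
  hit_cis <- !is.na(p) & scan$cis & p <= cis_cut
  hit_trans <- !is.na(p) & !scan$cis & p <= trans_cut
  for (j in which(colSums(hit_cis) > 0)) {
    cand <- which(hit_cis[, j])
    i <- cand[best_snp(p[cand, j], scan$snps$pos[cand], scan$snps$snp_id[cand])]
    rows[[length(rows) + 1L]] <- data.frame(
      probeset_id = scan$probesets$probeset_id[j],
      snp_id = scan$snps$snp_id[i], class = "cis", p = p[i, j],
      beta = scan$beta[i, j], r2 = scan$r2[i, j], cohort = cohort,
      fdr_level = target_of(thresholds$cis), stringsAsFactors = FALSE)
  }
  for (j in which(colSums(hit_trans) > 0)) {
    cand <- which(hit_trans[, j])
    for (ch in unique(scan$snps$chrom[cand])) {
      cc <- cand[scan$snps$chrom[cand] == ch]
      i <- cc[best_snp(p[cc, j], scan$snps$pos[cc], scan$snps$snp_id[cc])]
      rows[[length(rows) + 1L]] <- data.frame(
        probeset_id = scan$probesets$probeset_id[j],
        snp_id = scan$snps$snp_id[i], class = "trans", p = p[i, j],
        beta = scan$beta[i, j], r2 = scan$r2[i, j], cohort = cohort,
        fdr_level = target_of(thresholds$trans), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probeset_id = character(), snp_id = character(),
               class = character(), p = numeric(), beta = numeric(),
               r2 = numeric(), cohort = character(), fdr_level = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("eqtl_calls", "data.frame")
  out
}

#' Full per-cohort eQTL mapping
#'
#' Runs genotype QC, robust covariate adjustment, the exhaustive scan,
#' whole-sample label permutations (shared across probesets), class-specific
#' permutation FDR thresholds at the target rate, and best-eSNP calls.
#'
#' @param genotypes dosage matrix (SNPs x samples).
#' @param expression expression matrix (probesets x samples).
#' @param covariates covariate data frame (see [adjust_expression()]).
#' @param snps,probesets annotations.
#' @param cohort cohort label.
#' @param window cis window (bp).
#' @param fdr_target target FDR for eQTL declaration.
#' @param n_perm number of label permutations.
#' @param seed seed for the permutation indices.
#' @param call_rate_min,hwe_alpha genotype QC settings.
#' @param min_samples minimum pairs per association test.
#' @return object of class `cohort_eqtl`: scan, permutation scans (beta, se,
#'   p per permutation), thresholds, calls, QC report.
#' @export
map_cohort_eqtls <- function(genotypes, expression, covariates, snps,
                             probesets, cohort = "cohort", window = 1e6,
                             fdr_target = 0.10, n_perm = 5L, seed = 1L,
                             call_rate_min = 0.9, hwe_alpha = 1e-6,
                             min_samples = 30L) {
  qc <- qc_genotypes(genotypes, snps, call_rate_min, hwe_alpha)
  residuals <- adjust_expression(expression, covariates)
  scan <- eqtl_scan(qc$genotypes, residuals, qc$annotations, probesets,
                    window, min_samples)
  n <- ncol(residuals)
  perms <- lapply(seq_len(n_perm), function(r)
    with_seed(child_seed(seed, 100 + r), sample.int(n)))
  perm_scans <- lapply(perms, function(ix)
    fast_assoc_with_na(qc$genotypes, residuals[, ix, drop = FALSE],
                       min_samples))
  thresholds <- list(
    cis = estimate_fdr_threshold(scan$p[scan$cis],
                                 lapply(perm_scans, function(s) s$p[scan$cis]),
                                 fdr_target),
    trans = estimate_fdr_threshold(scan$p[!scan$cis],
                                   lapply(perm_scans, function(s) s$p[!scan$cis]),
                                   fdr_target))
  calls <- call_eqtls(scan, thresholds, cohort)
  structure(list(cohort = cohort, scan = scan, perm_scans = perm_scans,
                 perm_indices = perms, thresholds = thresholds,
                 calls = calls, qc_report = qc$report,
                 fdr_target = fdr_target),
            class = "cohort_eqtl")
}

# fast_assoc with the same missing-dosage handling as eqtl_scan, without r2.
fast_assoc_with_na <- function(genotypes, residuals, min_samples = 30L) {
  has_na <- rowSums(is.na(genotypes)) > 0
  G0 <- genotypes
  if (any(has_na)) G0[is.na(G0)] <- 0
  fa <- fast_assoc(G0, residuals, want_r2 = FALSE)
  for (i in which(has_na)) {
    ok <- !is.na(genotypes[i, ])
    if (sum(ok) < min_samples || diff(range(genotypes[i, ok])) == 0) {
      fa$beta[i, ] <- fa$se[i, ] <- fa$p[i, ] <- NA_real_
      next
    }
    sub <- fast_assoc(genotypes[i, ok, drop = FALSE],
                      residuals[, ok, drop = FALSE], want_r2 = FALSE)
    fa$beta[i, ] <- sub$beta; fa$se[i, ] <- sub$se; fa$p[i, ] <- sub$p
  }
  fa
}

#' @export
print.cohort_eqtl <- function(x, ...) {
  cat("Cohort", x$cohort, "eQTL mapping at", x$fdr_target * 100, "% FDR\n")
  cat("  QC kept", x$qc_report$n_kept, "of", x$qc_report$n_input, "SNPs\n")
  for (cl in c("cis", "trans")) {
    th <- x$thresholds[[cl]]
    cat(sprintf("  %-5s cutoff %.3g, %d calls\n", cl, th$p_cutoff,
                sum(x$calls$class == cl)))
  }
  invisible(x)
}
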