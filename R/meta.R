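# Cross-cohort combination: inverse-variance fixed effect, Cochran's Q and
# its chi-square P, the DerSimonian-Laird moment estimate of between-study
# variance, random-effects weights, and the replication rule.

#' Inverse-variance fixed-effect meta-analysis
#'
#' Weights each study by the inverse of its squared standard error:
#' w_i = 1/se_i^2, pooled effect sum(w b)/sum(w), pooled SE 1/sqrt(sum(w)),
#' two-sided P from the standard normal.
#'
#' @param betas per-study effect estimates.
#' @param ses per-study standard errors (all > 0).
#' @return list: beta, se, z, p, k.
#' @export
fixed_effect <- function(betas, ses) {
  ok <- !is.na(betas) & !is.na(ses)
  betas <- betas[ok]; ses <- ses[ok]
  if (length(betas) == 0) stop("no studies to combine")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
       k = length(betas))
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared differences between study effects and the pooled
#' fixed effect, with inverse-variance weights; under homogeneity Q follows
#' a chi-square with k - 1 degrees of freedom, giving the Q P-value.
#'
#' @inheritParams fixed_effect
#' @return list: q, df, q_pvalue (all NA when fewer than 2 studies).
#' @export
cochran_q <- function(betas, ses) {
  ok <- !is.na(betas) & !is.na(ses)
  betas <- betas[ok]; ses <- ses[ok]
  if (length(betas) < 2)
    return(list(q = NA_real_, df = NA_integer_, q_pvalue = NA_real_))
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - beta_fe)^2)
  df <- length(betas) - 1L
  list(q = q, df = df, q_pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))
#' with the fixed-effect weights w.
#'
#' @param q Cochran's Q.
#' @param df degrees of freedom (k - 1).
#' @param weights fixed-effect weights 1/se^2.
#' @return tau^2 (>= 0).
#' @export
tau_squared <- function(q, df, weights) {
  if (df < 1) stop("df must be >= 1")
  denom <- sum(weights) - sum(weights^2) / sum(weights)
  if (denom <= 0) {
    warning("degenerate weight configuration; tau2 set to 0")
    return(0)
  }
  max(0, (q - df) / denom)
}

#' Random-effects meta-analysis
#'
#' Inverse-variance pooling with the between-study variance added to each
#' study variance: w*_i = 1/(se_i^2 + tau2).
#'
#' @inheritParams fixed_effect
#' @param tau2 between-study variance; computed by the DerSimonian-Laird
#'   estimator from the data when omitted.
#' @return list: beta, se, z, p, tau2.
#' @export
random_effect <- function(betas, ses, tau2 = NULL) {
  ok <- !is.na(betas) & !is.na(ses)
  betas <- betas[ok]; ses <- ses[ok]
  if (length(betas) == 0) stop("no studies to combine")
  if (is.null(tau2)) {
    if (length(betas) < 2) tau2 <- 0
    else {
      cq <- cochran_q(betas, ses)
      tau2 <- tau_squared(cq$q, cq$df, 1 / ses^2)
    }
  }
  w <- 1 / (ses^2 + tau2)
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)), tau2 = tau2)
}

#' Combine both meta-analysis models and heterogeneity for one pair
#'
#' @inheritParams fixed_effect
#' @return one-row data frame with k, beta_fe, se_fe, p_fe, beta_re, se_re,
#'   p_re, q, q_df, q_pvalue, tau2, tau. With a single study the meta equals
#'   that study and the heterogeneity fields are NA.
#' @export
meta_analyse <- function(betas, ses) {
  fe <- fixed_effect(betas, ses)
  cq <- cochran_q(betas, ses)
  ok <- !is.na(betas) & !is.na(ses)
  tau2 <- if (is.na(cq$q)) NA_real_ else
    tau_squared(cq$q, cq$df, 1 / ses[ok]^2)
  re <- random_effect(betas, ses, tau2 = if (is.na(tau2)) 0 else tau2)
  data.frame(k = fe$k, beta_fe = fe$beta, se_fe = fe$se, p_fe = fe$p,
             beta_re = re$beta, se_re = re$se, p_re = re$p,
             q = cq$q, q_df = cq$df, q_pvalue = cq$q_pvalue,
             tau2 = tau2, tau = sqrt(ifelse(is.na(tau2), NA_real_, tau2)))
}

# Align a quantity matrix from each cohort's scan onto the union SNP set.
align_to_union <- function(mats, row_ids_list, union_ids) {
  lapply(seq_along(mats), function(k) {
    out <- matrix(NA_real_, length(union_ids), ncol(mats[[k]]))
    out[match(row_ids_list[[k]], union_ids), ] <- mats[[k]]
    out
  })
}

# Elementwise fixed-effect combination of aligned beta/se matrices.
# Returns beta_fe, se_fe, p_fe, k, q, q_pvalue, tau2 matrices.
combine_fixed <- function(beta_list, se_list, heterogeneity = TRUE) {
  K <- length(beta_list)
  dims <- dim(beta_list[[1]])
  sw <- swb <- sw2 <- kmat <- matrix(0, dims[1], dims[2])
  for (k in seq_len(K)) {
    w <- 1 / se_list[[k]]^2
    ok <- !is.na(w) & !is.na(beta_list[[k]])
    w[!ok] <- 0
    sw <- sw + w
    sw2 <- sw2 + w^2
    swb <- swb + ifelse(ok, w * beta_list[[k]], 0)
    kmat <- kmat + ok
  }
  beta_fe <- swb / sw
  se_fe <- 1 / sqrt(sw)
  z <- beta_fe / se_fe
  p_fe <- 2 * pnorm(-abs(z))
  none <- kmat == 0
  beta_fe[none] <- se_fe[none] <- p_fe[none] <- NA_real_
  out <- list(beta_fe = beta_fe, se_fe = se_fe, p_fe = p_fe, k = kmat)
  if (heterogeneity) {
    q <- matrix(0, dims[1], dims[2])
    for (k in seq_len(K)) {
      w <- 1 / se_list[[k]]^2
      ok <- !is.na(w) & !is.na(beta_list[[k]])
      d <- ifelse(ok, w * (beta_list[[k]] - beta_fe)^2, 0)
      q <- q + d
    }
    df <- kmat - 1
    q_pvalue <- matrix(NA_real_, dims[1], dims[2])
    multi <- df >= 1
    q_pvalue[multi] <- pchisq(q[multi], df[multi], lower.tail = FALSE)
    q[!multi] <- NA_real_
    denom <- sw - sw2 / sw
    tau2 <- (q - df) / denom
    tau2[!is.na(tau2) & tau2 < 0] <- 0
    tau2[multi & !(denom > 0)] <- 0
    tau2[!multi] <- NA_real_
    out$q <- q; out$q_pvalue <- q_pvalue; out$tau2 <- tau2
  }
  out
}

#' Meta-analytic eQTL scan across cohorts
#'
#' Combines per-cohort scan matrices pair-by-pair with the fixed-effect
#' model (k = cohorts contributing; pairs observed in a single cohort keep
#' that cohort's estimate), computes Cochran's Q, its P, and the
#' DerSimonian-Laird tau^2 and random-effects results, then derives
#' meta-level permutation FDR thresholds by combining each cohort's
#' label-permuted scans (the same permutation per cohort across the meta)
#' and declares meta-level eQTL calls.
#'
#' @param cohort_results list of `cohort_eqtl` objects from
#'   [map_cohort_eqtls()], sharing the probeset annotation.
#' @param fdr_target target FDR for meta-level calls.
#' @return object of class `meta_eqtl`: matrices (beta_fe, se_fe, p_fe,
#'   beta_re, se_re, p_re, q, q_pvalue, tau2, k), the union SNP annotation,
#'   thresholds, and calls.
#' @export
meta_scan <- function(cohort_results, fdr_target = 0.10) {
  stopifnot(length(cohort_results) >= 1)
  scans <- lapply(cohort_results, `[[`, "scan")
  probesets <- scans[[1]]$probesets
  ids_list <- lapply(scans, function(s) s$snps$snp_id)
  union_ids <- Reduce(union, ids_list)
  # keep the genomic order of the first cohort's annotation, then extras
  ann <- do.call(rbind, lapply(scans, `[[`, "snps"))
  ann <- ann[!duplicated(ann$snp_id), , drop = FALSE]
  if (nrow(ann) != length(union_ids))
    stop("allele/annotation mismatch between cohorts for SNP(s): ",
         paste(head(setdiff(union_ids, ann$snp_id)), collapse = ", "))
  union_ids <- ann$snp_id

  beta_list <- align_to_union(lapply(scans, `[[`, "beta"), ids_list, union_ids)
  se_list <- align_to_union(lapply(scans, `[[`, "se"), ids_list, union_ids)
  fe <- combine_fixed(beta_list, se_list)
  # random effects with the pairwise tau2
  swb <- sw <- matrix(0, length(union_ids), nrow(probesets))
  for (k in seq_along(beta_list)) {
    w <- 1 / (se_list[[k]]^2 + fe$tau2)
    ok <- !is.na(w) & !is.na(beta_list[[k]])
    w[!ok] <- 0
    sw <- sw + w
    swb <- swb + ifelse(ok, w * beta_list[[k]], 0)
  }
  beta_re <- swb / sw
  se_re <- 1 / sqrt(sw)
  p_re <- 2 * pnorm(-abs(beta_re / se_re))
  single <- fe$k <= 1
  beta_re[single] <- fe$beta_fe[single]
  se_re[single] <- fe$se_fe[single]
  p_re[single] <- fe$p_fe[single]

  cis <- cis_mask(ann, probesets, scans[[1]]$window)
  n_perm <- min(vapply(cohort_results, function(x) length(x$perm_scans), 0L))
  perm_p <- lapply(seq_len(n_perm), function(r) {
    pb <- align_to_union(lapply(cohort_results, function(x) x$perm_scans[[r]]$beta),
                         ids_list, union_ids)
    ps <- align_to_union(lapply(cohort_results, function(x) x$perm_scans[[r]]$se),
                         ids_list, union_ids)
    combine_fixed(pb, ps, heterogeneity = FALSE)$p_fe
  })
  thresholds <- list(
    cis = estimate_fdr_threshold(fe$p_fe[cis],
                                 lapply(perm_p, function(p) p[cis]), fdr_target),
    trans = estimate_fdr_threshold(fe$p_fe[!cis],
                                   lapply(perm_p, function(p) p[!cis]), fdr_target))
  pseudo <- structure(list(beta = fe$beta_fe, se = fe$se_fe, p = fe$p_fe,
                           r2 = matrix(NA_real_, nrow(fe$p_fe), ncol(fe$p_fe)),
                           n = rep(NA_integer_, nrow(fe$p_fe)), cis = cis,
                           snps = ann, probesets = probesets,
                           window = scans[[1]]$window),
                      class = "eqtl_scan")
  calls <- call_eqtls(pseudo, thresholds, cohort = "meta")
  structure(list(beta_fe = fe$beta_fe, se_fe = fe$se_fe, p_fe = fe$p_fe,
                 beta_re = beta_re, se_re = se_re, p_re = p_re,
                 q = fe$q, q_pvalue = fe$q_pvalue, tau2 = fe$tau2,
                 k = fe$k, cis = cis, snps = ann, probesets = probesets,
                 thresholds = thresholds, calls = calls,
                 cohorts = vapply(cohort_results, `[[`, "", "cohort"),
                 fdr_target = fdr_target),
            class = "meta_eqtl")
}

#' Extract meta-analysis records for chosen pairs
#'
#' @param meta a `meta_eqtl`.
#' @param snp_ids,probeset_ids equal-length identifier vectors naming the
#'   pairs.
#' @return data frame of MetaRecords (one row per pair).
#' @export
meta_records <- function(meta, snp_ids, probeset_ids) {
  i <- match(snp_ids, meta$snps$snp_id)
  j <- match(probeset_ids, meta$probesets$probeset_id)
  if (anyNA(i) || anyNA(j)) stop("unknown snp or probeset identifier")
  idx <- cbind(i, j)
  data.frame(snp_id = snp_ids, probeset_id = probeset_ids,
             k = meta$k[idx],
             beta_fe = meta$beta_fe[idx], se_fe = meta$se_fe[idx],
             p_fe = meta$p_fe[idx],
             beta_re = meta$beta_re[idx], se_re = meta$se_re[idx],
             p_re = meta$p_re[idx],
             q = meta$q[idx], q_pvalue = meta$q_pvalue[idx],
             tau2 = meta$tau2[idx], tau = sqrt(meta$tau2[idx]),
             stringsAsFactors = FALSE)
}

#' @export
print.meta_eqtl <- function(x, ...) {
  cat("Meta-analysis of", length(x$cohorts), "cohorts (",
      paste(x$cohorts, collapse = ", "), ")\n")
  for (cl in c("cis", "trans"))
    cat(sprintf("  %-5s cutoff %.3g, %d calls\n", cl,
                x$thresholds[[cl]]$p_cutoff, sum(x$calls$class == cl)))
  invisible(x)
}

#' Replication rule for one SNP-transcript pair
#'
#' Replicated if and only if at least two cohorts show the association with
#' the same effect sign at P at or below `alpha`.
#'
#' @param betas per-cohort effects.
#' @param ps per-cohort P-values.
#' @param alpha per-cohort significance level (default 1e-4).
#' @return logical flag.
#' @export
is_replicated <- function(betas, ps, alpha = 1e-4) {
  sig <- !is.na(ps) & ps <= alpha & !is.na(betas)
  if (sum(sig) < 2) return(FALSE)
  s <- sign(betas[sig])
  max(sum(s > 0), sum(s < 0)) >= 2
}

#' Cross-cohort replication of eQTL discoveries
#'
#' Applies the replication rule (same SNP-transcript pair, same effect sign,
#' P at or below `alpha` in more than one cohort) to every per-cohort eQTL
#' call and reports per-cohort replication rates.
#'
#' @param cohort_results list of `cohort_eqtl` objects.
#' @param alpha per-cohort significance level.
#' @return list of class `replication`: `records` data frame (probeset_id,
#'   snp_id, class, cohort, r2, cohorts_significant, replicated) and `rates`
#'   named per-cohort replication fractions.
#' @export
assess_replication <- function(cohort_results, alpha = 1e-4) {
  if (length(cohort_results) < 2) stop("need at least two cohorts")
  lookup <- lapply(cohort_results, function(x) {
    list(rows = x$scan$snps$snp_id, cols = x$scan$probesets$probeset_id,
         beta = x$scan$beta, p = x$scan$p)
  })
  names(lookup) <- vapply(cohort_results, `[[`, "", "cohort")
  calls <- do.call(rbind, lapply(cohort_results, `[[`, "calls"))
  if (nrow(calls) == 0)
    return(structure(list(records = calls, rates = setNames(
      rep(NA_real_, length(lookup)), names(lookup))), class = "replication"))
  recs <- lapply(seq_len(nrow(calls)), function(r) {
    snp <- calls$snp_id[r]; ps <- calls$probeset_id[r]
    betas <- pvals <- rep(NA_real_, length(lookup))
    for (k in seq_along(lookup)) {
      i <- match(snp, lookup[[k]]$rows); j <- match(ps, lookup[[k]]$cols)
      if (!is.na(i) && !is.na(j)) {
        betas[k] <- lookup[[k]]$beta[i, j]
        pvals[k] <- lookup[[k]]$p[i, j]
      }
    }
    sig <- which(!is.na(pvals) & pvals <= alpha)
    data.frame(probeset_id = ps, snp_id = snp, class = calls$class[r],
               cohort = calls$cohort[r], r2 = calls$r2[r],
               cohorts_significant = paste(names(lookup)[sig], collapse = ","),
               replicated = is_replicated(betas, pvals, alpha),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  rates <- vapply(names(lookup), function(nm) {
    own <- records$cohort == nm
    if (!any(own)) return(NA_real_)
    mean(records$replicated[own])
  }, 0)
  structure(list(records = records, rates = rates, alpha = alpha),
            class = "replication")
}

#' @export
print.replication <- function(x, ...) {
  cat("Replication at P <=", x$alpha, "in >1 cohort, same sign:\n")
  print(round(x$rates, 3))
  invisible(x)
}
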