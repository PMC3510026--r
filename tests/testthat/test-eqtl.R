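# Per-cohort mapping: genotype QC, robust adjustment, cis/trans
# classification, the association test against its closed form, the scan,
# permutation FDR thresholds, and best-eSNP calls.

test_that("genotype QC removes low call rate and HWE-deviant SNPs", {
  n <- 100
  g_ok <- rep(c(0, 1, 2), times = c(25, 50, 25))          # perfect HWE
  g_miss <- c(rep(NA, 50), rep(1, 50))                    # 50% missing
  g_hwe <- rep(c(0, 2), times = c(50, 50))                # no heterozygotes
  G <- rbind(g_miss, g_ok, g_hwe)
  ann <- data.frame(snp_id = c("s_miss", "s_ok", "s_hwe"))
  rownames(G) <- ann$snp_id
  qc <- qc_genotypes(G, ann)
  expect_identical(rownames(qc$genotypes), "s_ok")
  expect_identical(qc$report$n_removed_callrate, 1L)
  expect_identical(qc$report$n_removed_hwe, 1L)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_error(qc_genotypes(rbind(g_miss), ann[1, , drop = FALSE]),
               "no SNPs remain")
})

test_that("the exact HWE test matches independent enumeration and chi-square", {
  # independent enumeration: P(h het | allele counts) is multinomial with a
  # factor 2^h, written here with choose() rather than log-factorials
  enum_hwe <- function(a, h, b) {
    n <- a + h + b; rare <- 2 * min(a, b) + h
    hs <- seq(rare %% 2, rare, 2)
    pr <- vapply(hs, function(x) {
      ra <- (rare - x) / 2
      choose(n, ra) * choose(n - ra, x) * 2^x
    }, 0)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(h, hs)] * (1 + 1e-12)])
  }
  cases <- list(c(5, 10, 5), c(9, 2, 9), c(2, 16, 2), c(0, 4, 16),
                c(7, 0, 3))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 enum_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-10,
                 label = paste(cs, collapse = "/"))
  # perfectly balanced large sample sits at the mode: P-value 1
  expect_equal(hwe_exact_test(2500, 5000, 2500), 1, tolerance = 1e-9)
  # symmetric under swapping the homozygote classes
  expect_identical(hwe_exact_test(10, 3, 40), hwe_exact_test(40, 3, 10))
})

test_that("robust adjustment removes covariate signal and resists outliers", {
  set.seed(21)
  n <- 300
  cov <- data.frame(sample_id = seq_len(n), age = runif(n, 40, 80),
                    sex = rbinom(n, 1, 0.5),
                    smoking = sample(c("never", "ex", "current"), n, TRUE))
  y <- 1 + 0.05 * cov$age + 0.4 * cov$sex +
    0.3 * (cov$smoking == "current") + rnorm(n)
  res <- adjust_expression(matrix(y, 1, n), cov)
  expect_lt(abs(cor(res[1, ], cov$age)), 0.05)
  expect_equal(mean(res[1, ]), 0, tolerance = 1e-12)

  # an extreme outlier drags the OLS slope more than the Huber slope
  y2 <- 0.05 * cov$age + rnorm(n)
  y2[1] <- y2[1] + 20 * sd(y2)
  # fitted effect of age = y2 minus the robust residual; compare slope errors
  huber_fitted <- y2 - adjust_expression(matrix(y2, 1, n), cov)[1, ]
  huber_err <- abs(coef(lm(huber_fitted ~ cov$age))[2] - 0.05)
  ols_err <- abs(coef(lm(y2 ~ cov$age))[2] - 0.05)
  expect_lt(huber_err, ols_err)

  # agrees with the reference Huber M-estimator
  skip_if_not_installed("MASS")
  X <- cbind(cov$age, cov$sex, as.numeric(cov$smoking == "ex"),
             as.numeric(cov$smoking == "current"))
  f <- MASS::rlm(y2 ~ X, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  ref <- residuals(f) - mean(residuals(f))
  expect_equal(adjust_expression(matrix(y2, 1, n), cov)[1, ],
               ref, tolerance = 1e-3, ignore_attr = TRUE)

  # constant row: zero residuals with warning
  expect_warning(z <- adjust_expression(matrix(5, 1, n), cov), "constant")
  expect_true(all(z == 0))
  expect_error(adjust_expression(matrix(y, 1, n),
                                 transform(cov, smoking = "sometimes")),
               "smoking")
})

test_that("cis/trans classification is an inclusive 1 Mb window partition", {
  ps <- data.frame(probeset_id = "ps", chrom = "chr1",
                   start = 5e6, end = 5.01e6)
  snp_at <- function(pos, chrom = "chr1")
    data.frame(snp_id = "s", chrom = chrom, pos = pos)
  expect_identical(classify_pair(snp_at(5e6 - 1e6), ps), "cis")
  expect_identical(classify_pair(snp_at(5e6 - 1e6 - 1), ps), "trans")
  expect_identical(classify_pair(snp_at(5.01e6 + 1e6), ps), "cis")
  expect_identical(classify_pair(snp_at(5.01e6 + 1e6 + 1), ps), "trans")
  expect_identical(classify_pair(snp_at(5e6, "chr2"), ps), "trans")
  expect_error(classify_pair(snp_at(NA), ps), "missing position")
})

test_that("the association test equals its closed form and flags degeneracy", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 0.6, 1.1, -0.1, 0.4, 0.9)
  a <- test_association(g, y, min_samples = 3)
  expect_equal(a$beta, 0.5, tolerance = 1e-12)
  expect_equal(a$r2, 4 / 4.24, tolerance = 1e-12)
  expect_identical(a$n, 6L)

  b <- test_association(g, g, min_samples = 3)
  expect_equal(b$beta, 1, tolerance = 1e-12)
  expect_equal(b$r2, 1, tolerance = 1e-12)
  expect_error(test_association(rep(1, 10), rnorm(10), min_samples = 3),
               "monomorphic")
  expect_error(test_association(g, y, min_samples = 10), "min_samples")

  # random inputs: matches lm() to 1e-10
  set.seed(5)
  for (i in 1:10) {
    g <- rbinom(80, 2, 0.3); y <- 0.3 * g + rnorm(80)
    fit <- summary(lm(y ~ g))
    a <- test_association(g, y)
    expect_equal(a$beta, fit$coefficients["g", "Estimate"], tolerance = 1e-10)
    expect_equal(a$se, fit$coefficients["g", "Std. Error"], tolerance = 1e-10)
    expect_equal(a$p, fit$coefficients["g", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(a$r2, fit$r.squared, tolerance = 1e-10)
  }
})

test_that("the matrix scan agrees with per-pair tests and partitions pairs", {
  cfg <- small_cfg(seed = 31)
  st <- simulate_study(cfg)
  co <- st$cohorts[[1]]
  res <- adjust_expression(co$expression, co$covariates)
  # plant some missingness to exercise the pairwise-complete path
  G <- co$genotypes
  set.seed(31)
  G[5, sample(ncol(G), 10)] <- NA
  scan <- eqtl_scan(G, res, st$snps, st$probesets)
  expect_identical(dim(scan$p), c(nrow(G), nrow(res)))
  # every pair is exactly one of cis/trans
  expect_identical(sum(scan$cis) + sum(!scan$cis), length(scan$p))
  set.seed(32)
  for (idx in seq_len(12)) {
    i <- sample(nrow(G), 1); j <- sample(nrow(res), 1)
    a <- test_association(G[i, ], res[j, ])
    expect_equal(scan$beta[i, j], a$beta, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(scan$se[i, j], a$se, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(scan$p[i, j], a$p, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(scan$r2[i, j], a$r2, tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_identical(scan$n[5], ncol(G) - 10L)
  # permuting sample labels destroys the strongest planted association
  eff <- st$truth$effects
  cis_j <- which(eff$class == "cis")
  cis_i <- match(eff$snp_id[cis_j], st$snps$snp_id)
  planted_p <- scan$p[cbind(cis_i, cis_j)]
  j <- cis_j[which.min(planted_p)]
  i <- cis_i[which.min(planted_p)]
  expect_lt(scan$p[i, j], 1e-6)
  set.seed(33)
  perm <- sample(ncol(res))
  a_perm <- test_association(co$genotypes[i, ], res[j, perm])
  expect_gt(a_perm$p, 1e-4)
})

test_that("the permutation FDR threshold matches hand enumeration", {
  th <- estimate_fdr_threshold(c(0.001, 0.01, 0.02, 0.5),
                               list(c(0.03, 0.2, 0.6, 0.9)), 0.10)
  expect_equal(th$p_cutoff, 0.02)
  expect_identical(th$n_discoveries, 3L)
  # observed equals the null: nothing survives 10%
  null <- c(0.03, 0.2, 0.6, 0.9)
  expect_warning(th0 <- estimate_fdr_threshold(null, list(null), 0.10),
                 "cutoff set to 0")
  expect_equal(th0$p_cutoff, 0)
  expect_identical(th0$n_discoveries, 0L)
  # target 1: everything survives
  th1 <- estimate_fdr_threshold(c(0.001, 0.01, 0.02, 0.5),
                                list(c(0.03, 0.2, 0.6, 0.9)), 1.0)
  expect_equal(th1$p_cutoff, 0.5)
  expect_error(estimate_fdr_threshold(runif(5), list(), 0.1), "permutation")
})

test_that("eQTL calls apply the best-eSNP rule with deterministic tie-breaks", {
  scan <- tiny_scan()
  th <- list(cis = 1e-4, trans = 1e-4)
  calls <- call_eqtls(scan, th)
  # lowest-P cis SNP wins for ps1; at most one cis call per probeset
  expect_identical(calls$snp_id[calls$probeset_id == "ps1"], "snpA")
  expect_identical(sum(calls$probeset_id == "ps1" & calls$class == "cis"), 1L)
  # ps2's only sub-cutoff SNP is its cis snpC
  expect_identical(calls$snp_id[calls$probeset_id == "ps2"], "snpC")
  # tie in P: smaller genomic position wins
  p_tie <- matrix(c(1e-8, 1e-8, 0.5, 0.9, 0.9, 0.9), nrow = 3)
  tie_calls <- call_eqtls(tiny_scan(p_tie), th)
  expect_identical(tie_calls$snp_id[tie_calls$probeset_id == "ps1"], "snpA")
  # no sub-cutoff SNP: no call
  none <- call_eqtls(tiny_scan(matrix(0.5, 3, 2)), th)
  expect_identical(nrow(none), 0L)
})
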