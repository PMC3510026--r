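# Synthetic multi-cohort eQTL study generator.
#
# Emulates the statistical structure the downstream stages assume: Hardy-
# Weinberg genotypes at LD-free SNPs, expression with additive cis effects
# (SNP within 1 Mb of the probeset) and sparser trans effects, age/sex/smoking
# covariate effects, between-cohort effect heterogeneity, a sparse gene-
# regulatory DAG propagating expression signal, a canonical disease gene
# list, and GWAS P-values enriched at planted eSNPs.

#' Simulation configuration for a synthetic multi-cohort eQTL study
#'
#' Defaults describe the bundled study conditions: 3 cohorts of 300 samples,
#' 2,000 LD-free SNPs on 5 chromosomes of 10 Mb, 500 expression probesets,
#' planted cis effects sized so a single SNP explains roughly 10-20% of
#' transcript variance, and a 300-gene regulatory DAG with designated hubs.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort samples per cohort (scalar or length `n_cohorts`).
#' @param n_snps number of SNPs.
#' @param n_probesets number of expression probesets.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in base pairs.
#' @param maf_range interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param frac_cis fraction of probesets with a planted cis effect.
#' @param frac_trans fraction of probesets with a planted trans effect.
#' @param beta_cis,beta_trans planted effect sizes, expression units per
#'   alternate allele.
#' @param tau_het between-cohort standard deviation of true effects.
#' @param covariate_effects named coefficients for `age`, `sex`,
#'   `smoking_ex`, `smoking_current`.
#' @param noise_sd residual standard deviation of expression.
#' @param network_genes number of genes in the regulatory DAG (first
#'   `network_genes` probesets' gene symbols).
#' @param max_parents maximum in-degree in the DAG.
#' @param n_hubs number of designated high out-degree hub nodes.
#' @param hub_children forced out-degree of each hub.
#' @param edge_weight_range interval for DAG edge weights.
#' @param canonical_size size of the canonical disease gene list.
#' @param canonical_hub_frac fraction of the canonical list drawn from hub
#'   descendants (concentrates the list in network neighborhoods, as a
#'   literature-curated disease list is).
#' @param gwas_enrichment_frac fraction of planted eSNPs whose GWAS P-value
#'   is drawn from the enriched (stochastically smaller) law.
#' @param gwas_beta_shape shape `a` of the Beta(a, 1) law for enriched GWAS
#'   P-values.
#' @param seed integer seed; fixing it makes every product byte-identical.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3,
                       samples_per_cohort = 300,
                       n_snps = 2000,
                       n_probesets = 500,
                       n_chromosomes = 5,
                       chrom_length = 1e7,
                       maf_range = c(0.1, 0.5),
                       frac_cis = 0.35,
                       frac_trans = 0.05,
                       beta_cis = 0.65,
                       beta_trans = 0.8,
                       tau_het = 0.1,
                       covariate_effects = c(age = 0.02, sex = 0.5,
                                             smoking_ex = 0.3,
                                             smoking_current = 0.6),
                       noise_sd = 1,
                       network_genes = 300,
                       max_parents = 2,
                       n_hubs = 3,
                       hub_children = 12,
                       edge_weight_range = c(0.4, 0.8),
                       canonical_size = 119,
                       canonical_hub_frac = 0.4,
                       gwas_enrichment_frac = 0.3,
                       gwas_beta_shape = 0.2,
                       seed = 1L) {
  if (length(samples_per_cohort) == 1L)
    samples_per_cohort <- rep(samples_per_cohort, n_cohorts)
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_snps = as.integer(n_snps),
              n_probesets = as.integer(n_probesets),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              maf_range = as.numeric(maf_range),
              frac_cis = frac_cis, frac_trans = frac_trans,
              beta_cis = beta_cis, beta_trans = beta_trans,
              tau_het = tau_het,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              network_genes = as.integer(network_genes),
              max_parents = as.integer(max_parents),
              n_hubs = as.integer(n_hubs),
              hub_children = as.integer(hub_children),
              edge_weight_range = as.numeric(edge_weight_range),
              canonical_size = as.integer(canonical_size),
              canonical_hub_frac = canonical_hub_frac,
              gwas_enrichment_frac = gwas_enrichment_frac,
              gwas_beta_shape = gwas_beta_shape,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_cohorts, cfg$samples_per_cohort, cfg$n_snps,
              cfg$n_probesets, cfg$n_chromosomes, cfg$chrom_length)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (length(cfg$samples_per_cohort) != cfg$n_cohorts)
    stop("samples_per_cohort must have one entry per cohort")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$frac_cis < 0 || cfg$frac_trans < 0 ||
      cfg$frac_cis + cfg$frac_trans > 1)
    stop("frac_cis + frac_trans must not exceed 1")
  if (cfg$network_genes > cfg$n_probesets)
    stop("network_genes must not exceed n_probesets")
  if (cfg$canonical_size > cfg$n_probesets)
    stop("canonical_size must not exceed the number of genes")
  if (cfg$tau_het < 0 || cfg$noise_sd <= 0)
    stop("tau_het must be >= 0 and noise_sd > 0")
  invisible(TRUE)
}

#' Effect size giving a target per-SNP variance explained
#'
#' Inverts R2 = b^2 V / (b^2 V + noise_sd^2) with V = 2 p (1 - p), the
#' additive dosage variance under Hardy-Weinberg at allele frequency `p`.
#'
#' @param r2 target fraction of expression variance explained.
#' @param maf allele frequency.
#' @param noise_sd residual standard deviation.
#' @return effect size in expression units per allele.
#' @export
beta_for_r2 <- function(r2, maf, noise_sd = 1) {
  v <- 2 * maf * (1 - maf)
  noise_sd * sqrt(r2 / ((1 - r2) * v))
}

#' Simulate SNP annotations
#'
#' SNP positions are uniform on the chromosomes (1-based); per-SNP allele
#' frequencies are uniform on `maf_range`. Annotations are shared by all
#' cohorts.
#'
#' @param cfg a [sim_config()].
#' @return data frame with snp_id, chrom, pos, ref, alt, maf.
#' @export
simulate_snp_annotations <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1), {
    bases <- c("A", "C", "G", "T")
    chrom <- sort(sample.int(cfg$n_chromosomes, cfg$n_snps, replace = TRUE))
    pos <- integer(cfg$n_snps)
    for (ch in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(cfg$chrom_length, length(idx)))
    }
    ref <- sample(bases, cfg$n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(snp_id = sprintf("snp%05d", seq_len(cfg$n_snps)),
               chrom = paste0("chr", chrom), pos = pos,
               ref = ref, alt = unname(alt),
               maf = runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate probeset annotations
#'
#' Each probeset maps to one gene symbol and a genomic interval (1-based,
#' inclusive) on a simulated chromosome.
#'
#' @param cfg a [sim_config()].
#' @return data frame with probeset_id, gene_symbol, chrom, start, end, strand.
#' @export
simulate_probeset_annotations <- function(cfg) {
  with_seed(child_seed(cfg$seed, 2), {
    chrom <- sort(sample.int(cfg$n_chromosomes, cfg$n_probesets, replace = TRUE))
    len <- sample(1000:50000, cfg$n_probesets, replace = TRUE)
    start <- integer(cfg$n_probesets)
    for (ch in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom == ch)
      start[idx] <- sort(sample.int(cfg$chrom_length - max(len), length(idx)))
    }
    data.frame(probeset_id = sprintf("ps%04d", seq_len(cfg$n_probesets)),
               gene_symbol = sprintf("G%04d", seq_len(cfg$n_probesets)),
               chrom = paste0("chr", chrom), start = start,
               end = start + len - 1L,
               strand = sample(c("+", "-"), cfg$n_probesets, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate Hardy-Weinberg genotype dosages for one cohort
#'
#' Dosages in \{0, 1, 2\} are drawn per SNP as Binomial(2, maf): exact
#' Hardy-Weinberg proportions. SNPs are mutually independent (no LD).
#'
#' @param cfg a [sim_config()].
#' @param cohort cohort index (1-based).
#' @param snps SNP annotations from [simulate_snp_annotations()]; generated
#'   from `cfg` if omitted.
#' @return integer matrix SNPs x samples with dimnames.
#' @export
simulate_genotypes <- function(cfg, cohort, snps = NULL) {
  if (is.null(snps)) snps <- simulate_snp_annotations(cfg)
  stopifnot(cohort >= 1, cohort <= cfg$n_cohorts)
  n <- cfg$samples_per_cohort[cohort]
  with_seed(child_seed(cfg$seed, 10 + cohort), {
    g <- matrix(rbinom(cfg$n_snps * n, 2L, rep(snps$maf, times = n)),
                nrow = cfg$n_snps, ncol = n)
    dimnames(g) <- list(snps$snp_id,
                        sprintf("c%d_s%03d", cohort, seq_len(n)))
    g
  })
}

#' Simulate the planted ground truth
#'
#' Assigns a cis effect SNP (within the 1 Mb window) to `frac_cis` of
#' probesets and a trans SNP (outside it) to `frac_trans`; draws the global
#' effect and per-cohort effects global + N(0, tau_het^2).
#'
#' @param cfg a [sim_config()].
#' @param snps,probesets annotations; generated from `cfg` if omitted.
#' @param window cis window in base pairs.
#' @return list of class `truth_table`: per-probeset data frame `effects`
#'   (probeset_id, snp_id, class, beta_global) and matrix `beta_cohort`
#'   (probesets x cohorts).
#' @export
simulate_truth <- function(cfg, snps = NULL, probesets = NULL,
                           window = 1e6) {
  if (is.null(snps)) snps <- simulate_snp_annotations(cfg)
  if (is.null(probesets)) probesets <- simulate_probeset_annotations(cfg)
  with_seed(child_seed(cfg$seed, 3), {
    np <- cfg$n_probesets
    n_cis <- round(cfg$frac_cis * np)
    n_trans <- round(cfg$frac_trans * np)
    cls <- rep("none", np)
    pick <- sample.int(np, n_cis + n_trans)
    cls[pick[seq_len(n_cis)]] <- "cis"
    if (n_trans > 0) cls[pick[n_cis + seq_len(n_trans)]] <- "trans"

    snp_id <- rep(NA_character_, np)
    beta_global <- rep(0, np)
    for (j in seq_len(np)) {
      if (cls[j] == "none") next
      in_window <- snps$chrom == probesets$chrom[j] &
        snps$pos >= probesets$start[j] - window &
        snps$pos <= probesets$end[j] + window
      eligible <- if (cls[j] == "cis") which(in_window) else which(!in_window)
      if (length(eligible) == 0L) { cls[j] <- "none"; next }
      snp_id[j] <- snps$snp_id[eligible[sample.int(length(eligible), 1L)]]
      b <- if (cls[j] == "cis") cfg$beta_cis else cfg$beta_trans
      beta_global[j] <- b * sample(c(-1, 1), 1L)
    }
    beta_cohort <- matrix(0, np, cfg$n_cohorts,
                          dimnames = list(probesets$probeset_id,
                                          paste0("cohort", seq_len(cfg$n_cohorts))))
    planted <- cls != "none"
    for (k in seq_len(cfg$n_cohorts))
      beta_cohort[planted, k] <- beta_global[planted] +
        rnorm(sum(planted), 0, cfg$tau_het)
    structure(list(
      effects = data.frame(probeset_id = probesets$probeset_id,
                           snp_id = snp_id, class = cls,
                           beta_global = beta_global,
                           stringsAsFactors = FALSE),
      beta_cohort = beta_cohort, window = window),
      class = "truth_table")
  })
}

#' Simulate a sparse gene-regulatory DAG
#'
#' Nodes (the first `network_genes` gene symbols) are topologically ordered;
#' each draws at most `max_parents` parents from earlier nodes, which
#' guarantees acyclicity. `n_hubs` designated hub nodes are forced to an
#' out-degree of `hub_children`, far above the median, to exercise key
#' driver analysis.
#'
#' @param cfg a [sim_config()].
#' @param probesets probeset annotations; generated from `cfg` if omitted.
#' @return list of class `sim_network`: `edges` data frame (parent_gene,
#'   child_gene, weight), `genes`, `hubs`, and per-node `parents` list.
#' @export
simulate_network <- function(cfg, probesets = NULL) {
  if (is.null(probesets)) probesets <- simulate_probeset_annotations(cfg)
  genes <- probesets$gene_symbol[seq_len(cfg$network_genes)]
  G <- cfg$network_genes
  with_seed(child_seed(cfg$seed, 4), {
    parents <- vector("list", G)
    weights <- vector("list", G)
    hubs <- if (cfg$n_hubs > 0) seq_len(min(cfg$n_hubs, G)) else integer()
    # hub fan-out first, then random fill respecting the in-degree cap
    for (h in hubs) {
      kids <- setdiff(seq_len(G), seq_len(h))
      kids <- kids[kids > max(hubs)]
      if (length(kids) == 0) next
      kids <- sample(kids, min(cfg$hub_children, length(kids)))
      for (k in kids) parents[[k]] <- c(parents[[k]], h)
    }
    if (cfg$max_parents > 0) {
      for (j in seq(2L, length.out = G - 1L)) {
        room <- cfg$max_parents - length(parents[[j]])
        if (room <= 0) { parents[[j]] <- parents[[j]][seq_len(cfg$max_parents)]; next }
        npar <- sample.int(room + 1L, 1L) - 1L
        pool <- setdiff(seq_len(j - 1L), parents[[j]])
        if (npar > 0 && length(pool) > 0)
          parents[[j]] <- c(parents[[j]],
                            pool[sample.int(length(pool), min(npar, length(pool)))])
      }
    } else {
      parents <- rep(list(integer()), G)
    }
    for (j in seq_len(G))
      weights[[j]] <- runif(length(parents[[j]]),
                            cfg$edge_weight_range[1], cfg$edge_weight_range[2])
    edges <- do.call(rbind, lapply(seq_len(G), function(j) {
      if (length(parents[[j]]) == 0) return(NULL)
      data.frame(parent_gene = genes[parents[[j]]], child_gene = genes[j],
                 weight = weights[[j]], stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
      edges <- data.frame(parent_gene = character(), child_gene = character(),
                          weight = numeric())
    structure(list(edges = edges, genes = genes, hubs = genes[hubs],
                   parents = parents, weights = weights),
              class = "sim_network")
  })
}

#' Simulate expression, covariates, and noise for one cohort
#'
#' Expression is covariate term + per-cohort true effect x dosage +
#' propagated DAG parent signal + N(0, noise_sd^2). Covariates: age uniform
#' on 40-80 years, sex Bernoulli(0.5), smoking 3-level (never/ex/current).
#'
#' @param cfg a [sim_config()].
#' @param genotypes dosage matrix for the cohort from [simulate_genotypes()].
#' @param cohort cohort index.
#' @param truth a `truth_table`; generated from `cfg` if omitted.
#' @param network a `sim_network` or NULL to skip DAG propagation; generated
#'   from `cfg` if missing.
#' @param probesets probeset annotations; generated from `cfg` if omitted.
#' @return list: `expression` (probesets x samples), `covariates` data frame
#'   (sample_id, age, sex, smoking), `truth`.
#' @export
simulate_expression <- function(cfg, genotypes, cohort, truth = NULL,
                                network, probesets = NULL) {
  if (is.null(probesets)) probesets <- simulate_probeset_annotations(cfg)
  if (is.null(truth)) truth <- simulate_truth(cfg, probesets = probesets)
  if (missing(network)) network <- simulate_network(cfg, probesets)
  n <- ncol(genotypes)
  if (n != cfg$samples_per_cohort[cohort])
    stop("genotype matrix does not match cfg sample count for cohort ", cohort)
  with_seed(child_seed(cfg$seed, 20 + cohort), {
    age <- runif(n, 40, 80)
    sex <- rbinom(n, 1L, 0.5)
    smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
    ce <- cfg$covariate_effects
    cov_term <- ce[["age"]] * age + ce[["sex"]] * sex +
      ce[["smoking_ex"]] * (smoking == "ex") +
      ce[["smoking_current"]] * (smoking == "current")

    S <- matrix(rnorm(cfg$n_probesets * n, 0, cfg$noise_sd),
                cfg$n_probesets, n)
    eff <- truth$effects
    planted <- which(eff$class != "none")
    for (j in planted) {
      b <- truth$beta_cohort[j, cohort]
      S[j, ] <- S[j, ] + b * genotypes[eff$snp_id[j], ]
    }
    if (!is.null(network)) {
      for (j in seq_along(network$parents)) {
        ps <- network$parents[[j]]
        if (length(ps) == 0) next
        S[j, ] <- S[j, ] + as.vector(network$weights[[j]] %*% S[ps, , drop = FALSE])
      }
    }
    expr <- sweep(S, 2L, cov_term, `+`)
    dimnames(expr) <- list(probesets$probeset_id, colnames(genotypes))
    covariates <- data.frame(sample_id = colnames(genotypes),
                             age = age, sex = sex, smoking = smoking,
                             stringsAsFactors = FALSE)
    list(expression = expr, covariates = covariates, truth = truth)
  })
}

#' Simulate the canonical disease gene list
#'
#' Draws `canonical_size` gene symbols, a configurable fraction from hub
#' descendants in the regulatory DAG so the list concentrates in network
#' neighborhoods the way a curated disease list does.
#'
#' @param cfg a [sim_config()].
#' @param network a `sim_network`.
#' @return character vector of gene symbols.
#' @export
simulate_canonical <- function(cfg, network) {
  with_seed(child_seed(cfg$seed, 5), {
    genes <- network$genes
    desc <- hub_descendants(network)
    n_hub <- min(length(desc), round(cfg$canonical_hub_frac * cfg$canonical_size))
    sel <- if (n_hub > 0) sample(desc, n_hub) else character()
    pool <- setdiff(genes, sel)
    need <- cfg$canonical_size - length(sel)
    if (need > length(pool)) stop("canonical_size exceeds available genes")
    sort(c(sel, sample(pool, need)))
  })
}

# All genes reachable downstream of any hub (hub excluded).
hub_descendants <- function(network) {
  G <- length(network$genes)
  children <- vector("list", G)
  for (j in seq_len(G)) for (p in network$parents[[j]])
    children[[p]] <- c(children[[p]], j)
  hubs <- match(network$hubs, network$genes)
  seen <- logical(G)
  frontier <- hubs
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[hubs] <- FALSE
  network$genes[seen]
}

#' Truly associated SNP-probeset pairs of a simulated study
#'
#' Ground truth for recovery and false-discovery evaluation: each planted
#' (SNP, probeset) pair, plus the same SNP paired with every DAG descendant
#' of the planted probeset, since the generator propagates expression
#' signal (and with it any genetic effect) down the regulatory network.
#'
#' @param study an `eqtl_study`.
#' @return data frame snp_id, probeset_id with one row per truly
#'   associated pair.
#' @export
true_pairs <- function(study) {
  eff <- study$truth$effects
  planted <- which(eff$class != "none")
  G <- length(study$network$genes)
  children <- vector("list", G)
  for (j in seq_len(G)) for (p in study$network$parents[[j]])
    children[[p]] <- c(children[[p]], j)
  desc_of <- function(j) {
    seen <- logical(G); frontier <- j
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(children[frontier])), which(seen))
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  }
  rows <- lapply(planted, function(j) {
    ps <- j
    if (j <= G) ps <- c(j, desc_of(j))
    data.frame(snp_id = eff$snp_id[j],
               probeset_id = study$probesets$probeset_id[ps],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out), , drop = FALSE]
}

#' Simulate GWAS summary statistics
#'
#' Non-eSNPs receive P ~ Uniform(0, 1); a configured fraction of planted
#' effect SNPs receive P ~ Beta(a, 1) with a < 1, a stochastically smaller
#' law, so the table is enriched for low P at eSNPs and has SNPs on both
#' sides of any downstream P threshold.
#'
#' @param cfg a [sim_config()].
#' @param truth a `truth_table`.
#' @param snps SNP annotations; generated from `cfg` if omitted.
#' @return data frame snp_id, chrom, pos, p, effect_allele.
#' @export
simulate_gwas <- function(cfg, truth, snps = NULL) {
  if (is.null(snps)) snps <- simulate_snp_annotations(cfg)
  with_seed(child_seed(cfg$seed, 6), {
    p <- runif(cfg$n_snps)
    esnps <- unique(truth$effects$snp_id[truth$effects$class != "none"])
    esnps <- esnps[!is.na(esnps)]
    if (length(esnps) > 0 && cfg$gwas_enrichment_frac > 0) {
      n_enr <- round(cfg$gwas_enrichment_frac * length(esnps))
      if (n_enr > 0) {
        enr <- sample(esnps, n_enr)
        idx <- match(enr, snps$snp_id)
        p[idx] <- rbeta(n_enr, cfg$gwas_beta_shape, 1)
      }
    }
    data.frame(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
               p = p, effect_allele = snps$alt, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete multi-cohort study
#'
#' Orchestrates annotations, truth, per-cohort genotypes/expression/
#' covariates, the regulatory DAG, the canonical gene list, and GWAS summary
#' statistics. Identical configuration (including seed) yields identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `eqtl_study` with elements snps, probesets, truth,
#'   network, canonical, gwas, cohorts (each: genotypes, expression,
#'   covariates).
#' @export
simulate_study <- function(cfg) {
  snps <- simulate_snp_annotations(cfg)
  probesets <- simulate_probeset_annotations(cfg)
  truth <- simulate_truth(cfg, snps, probesets)
  network <- simulate_network(cfg, probesets)
  canonical <- simulate_canonical(cfg, network)
  gwas <- simulate_gwas(cfg, truth, snps)
  cohorts <- lapply(seq_len(cfg$n_cohorts), function(k) {
    g <- simulate_genotypes(cfg, k, snps)
    e <- simulate_expression(cfg, g, k, truth, network, probesets)
    list(genotypes = g, expression = e$expression,
         covariates = e$covariates)
  })
  names(cohorts) <- paste0("cohort", seq_len(cfg$n_cohorts))
  structure(list(config = cfg, snps = snps, probesets = probesets,
                 truth = truth, network = network, canonical = canonical,
                 gwas = gwas, cohorts = cohorts),
            class = "eqtl_study")
}

#' @export
print.eqtl_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic eQTL study:", cfg$n_cohorts, "cohorts (",
      paste(cfg$samples_per_cohort, collapse = "/"), "samples ),",
      cfg$n_snps, "SNPs,", cfg$n_probesets, "probesets\n")
  eff <- table(x$truth$effects$class)
  cat("Planted effects:", paste(names(eff), eff, collapse = ", "), "\n")
  cat("Network:", length(x$network$genes), "genes,",
      nrow(x$network$edges), "edges; canonical list:",
      length(x$canonical), "genes\n")
  invisible(x)
}

#' Write a simulated study to disk as headered TSV / text files
#'
#' Emits genotypes_<cohort>.tsv, expression_<cohort>.tsv,
#' covariates_<cohort>.tsv, snps.tsv, probesets.tsv, gwas.tsv, network.tsv,
#' canonical.txt, and truth.json under `dir`.
#'
#' @param study an `eqtl_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_tsv(study$snps, fp("snps.tsv"))
  write_tsv(study$probesets, fp("probesets.tsv"))
  write_tsv(study$gwas, fp("gwas.tsv"))
  write_tsv(study$network$edges[, c("parent_gene", "child_gene")],
            fp("network.tsv"))
  writeLines(study$canonical, fp("canonical.txt"))
  for (nm in names(study$cohorts)) {
    co <- study$cohorts[[nm]]
    g <- data.frame(snp_id = rownames(co$genotypes), co$genotypes,
                    check.names = FALSE)
    write_tsv(g, fp(paste0("genotypes_", nm, ".tsv")))
    e <- data.frame(probeset_id = rownames(co$expression), co$expression,
                    check.names = FALSE)
    write_tsv(e, fp(paste0("expression_", nm, ".tsv")))
    write_tsv(co$covariates, fp(paste0("covariates_", nm, ".tsv")))
  }
  truth <- list(effects = study$truth$effects,
                beta_cohort = as.data.frame(study$truth$beta_cohort),
                window = study$truth$window)
  jsonlite::write_json(truth, fp("truth.json"), digits = NA, na = "null")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' Restores the annotations, GWAS table, network edge list, canonical gene
#' list, per-cohort matrices, and (when present) the planted truth. The
#' generator configuration is not stored on disk, so `config` is `NULL` in
#' the result.
#'
#' @param dir directory produced by [write_study()].
#' @return list of class `eqtl_study`.
#' @export
read_study <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  need <- c("snps.tsv", "probesets.tsv", "gwas.tsv", "network.tsv",
            "canonical.txt")
  missing <- need[!file.exists(fp(need))]
  if (length(missing))
    stop("not a study directory; missing: ", paste(missing, collapse = ", "))
  snps <- read_tsv(fp("snps.tsv"))
  probesets <- read_tsv(fp("probesets.tsv"))
  as_mat <- function(df, id_col) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[id_col]]
    m
  }
  cohort_files <- list.files(dir, pattern = "^genotypes_.*\\.tsv$")
  cohort_names <- sub("^genotypes_(.*)\\.tsv$", "\\1", cohort_files)
  cohorts <- lapply(cohort_names, function(nm) {
    list(genotypes = as_mat(read_tsv(fp(paste0("genotypes_", nm, ".tsv"))),
                            "snp_id"),
         expression = as_mat(read_tsv(fp(paste0("expression_", nm, ".tsv"))),
                             "probeset_id"),
         covariates = read_tsv(fp(paste0("covariates_", nm, ".tsv"))))
  })
  names(cohorts) <- cohort_names
  truth <- NULL
  if (file.exists(fp("truth.json"))) {
    tj <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
    truth <- list(effects = tj$effects,
                  beta_cohort = as.matrix(tj$beta_cohort),
                  window = tj$window)
  }
  structure(list(config = NULL, snps = snps, probesets = probesets,
                 truth = truth,
                 network = list(edges = read_tsv(fp("network.tsv")),
                                genes = NULL, hubs = NULL),
                 canonical = readLines(fp("canonical.txt")),
                 gwas = read_tsv(fp("gwas.tsv")), cohorts = cohorts),
            class = "eqtl_study")
}
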