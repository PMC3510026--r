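# End-to-end orchestration: configuration, the full synthetic-study driver
# (simulate -> QC -> adjust -> scan -> FDR -> meta -> replication -> GWAS
# integration -> subnetwork -> KDA -> locus ranking), and report rendering.

#' Pipeline run configuration
#'
#' Bundles the analysis constants (1 Mb cis window, 10% FDR, replication
#' P <= 1e-4, GWAS P < 0.01, 3-edge neighborhoods, KDA alpha 0.05) with the
#' synthetic-study configuration. Serializes losslessly to JSON via
#' [write_pipeline_config()].
#'
#' @param sim a [sim_config()] (its seed is re-derived from `seed`).
#' @param window cis window in base pairs.
#' @param fdr_target FDR for eQTL declaration.
#' @param alpha_rep per-cohort replication significance level.
#' @param gwas_threshold strict GWAS P cutoff for SNP-to-gene translation.
#' @param h network neighborhood radius in edges.
#' @param kda_alpha significance level for key drivers (adjusted P).
#' @param n_perm label permutations for the FDR thresholds.
#' @param seed master seed for simulation and permutations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed), window = 1e6,
                            fdr_target = 0.10, alpha_rep = 1e-4,
                            gwas_threshold = 0.01, h = 3, kda_alpha = 0.05,
                            n_perm = 5L, seed = 1L) {
  thr <- c(fdr_target = fdr_target, alpha_rep = alpha_rep,
           gwas_threshold = gwas_threshold, kda_alpha = kda_alpha)
  if (any(thr <= 0 | thr >= 1)) stop("all thresholds must lie in (0, 1)")
  if (window <= 0) stop("window must be positive")
  structure(list(sim = sim, window = window, fdr_target = fdr_target,
                 alpha_rep = alpha_rep, gwas_threshold = gwas_threshold,
                 h = h, kda_alpha = kda_alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return the path (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # keep the covariate names through JSON (objects keep keys, arrays do not)
  x$sim$covariate_effects <- as.list(x$sim$covariate_effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- x$sim
  sim$covariate_effects <- unlist(sim$covariate_effects)
  cfg <- do.call(sim_config, sim)
  pipeline_config(sim = cfg, window = x$window, fdr_target = x$fdr_target,
                  alpha_rep = x$alpha_rep, gwas_threshold = x$gwas_threshold,
                  h = x$h, kda_alpha = x$kda_alpha, n_perm = x$n_perm,
                  seed = x$seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a (simulated or supplied) study
#'
#' Executes simulate, per-cohort QC/adjust/scan/FDR/calls, meta-analysis,
#' replication, GWAS integration, coherent-subnetwork extraction, key
#' driver analysis, and locus-candidate ranking, and assembles a run
#' summary with the counts at each stage. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param study an existing `eqtl_study`; simulated from `config$sim` when
#'   omitted.
#' @param out optional output directory; when given, all declared TSV/JSON
#'   products are written there.
#' @return object of class `eqtl_pipeline` with all stage results and
#'   `$summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         out = NULL) {
  if (is.null(study))
    study <- stage("simulate", simulate_study(config$sim))
  cohorts <- stage("eqtl", {
    lapply(seq_along(study$cohorts), function(k) {
      co <- study$cohorts[[k]]
      map_cohort_eqtls(co$genotypes, co$expression, co$covariates,
                       study$snps, study$probesets,
                       cohort = names(study$cohorts)[k],
                       window = config$window,
                       fdr_target = config$fdr_target,
                       n_perm = config$n_perm,
                       seed = child_seed(config$seed, 7000 + k))
    })
  })
  meta <- stage("meta", meta_scan(cohorts, config$fdr_target))
  replication <- stage("replicate", assess_replication(cohorts, config$alpha_rep))
  esnp <- stage("integrate", build_esnp_set(meta))
  have_esnps <- length(esnp$snps) >= 10
  qq <- if (have_esnps)
    stage("integrate", enrichment_qq(study$gwas, esnp)) else NULL
  links <- stage("integrate",
                 link_gwas_genes(study$gwas, esnp, config$gwas_threshold))
  net <- stage("network", load_network(study$network$edges[, 1:2]))
  seed_genes <- intersect(toupper(links$genes), igraph::V(net)$name)
  subnet <- if (length(seed_genes) > 0)
    stage("subnet", extract_subnetwork(net, seed_genes, config$h)) else NULL
  kda <- if (length(seed_genes) > 0)
    stage("kda", key_driver_analysis(net, seed_genes, config$h,
                                     config$kda_alpha)) else NULL
  locus <- if (length(seed_genes) > 0)
    stage("rank-locus", rank_locus_candidates(net, seed_genes,
                                              study$canonical, config$h))
    else NULL

  call_count <- function(calls, cl) sum(calls$class == cl)
  summary <- list(
    seed = config$seed,
    cohorts = lapply(cohorts, function(x) list(
      cohort = x$cohort,
      cis_cutoff = x$thresholds$cis$p_cutoff,
      cis_calls = call_count(x$calls, "cis"),
      trans_cutoff = x$thresholds$trans$p_cutoff,
      trans_calls = call_count(x$calls, "trans"))),
    meta = list(cohort = "meta",
                cis_cutoff = meta$thresholds$cis$p_cutoff,
                cis_calls = call_count(meta$calls, "cis"),
                trans_cutoff = meta$thresholds$trans$p_cutoff,
                trans_calls = call_count(meta$calls, "trans")),
    replication_rates = as.list(replication$rates),
    n_esnps = length(esnp$snps),
    enrichment_p = if (!is.null(qq)) qq$enrichment_p else NA,
    n_gwas_linked_snps = links$n_snps,
    n_linked_genes = length(links$genes),
    subnetwork_size = if (!is.null(subnet)) subnet$size else 0L,
    subnetwork_seed_proportion = if (!is.null(subnet)) subnet$proportion else NA,
    n_key_drivers = if (!is.null(kda)) length(kda$drivers) else 0L,
    key_drivers = if (!is.null(kda)) kda$drivers else character())

  result <- structure(list(config = config, study = study,
                           cohorts = cohorts, meta = meta,
                           replication = replication, esnp_set = esnp,
                           qq = qq, links = links, network = net,
                           subnetwork = subnet, kda = kda,
                           locus_ranking = locus, summary = summary),
                      class = "eqtl_pipeline")
  if (!is.null(out)) write_pipeline_outputs(result, out)
  result
}

#' Write all declared pipeline output files
#'
#' @param result an `eqtl_pipeline`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  thr_rows <- list()
  for (x in result$cohorts) {
    write_tsv(x$calls, fp(paste0("eqtl_calls_", x$cohort, ".tsv")))
    write_tsv(assoc_table(x$scan, p_max = 1e-3, cohort = x$cohort),
              fp(paste0("assoc_top_", x$cohort, ".tsv")))
    for (cl in c("cis", "trans"))
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        cohort = x$cohort, class = cl,
        p_cutoff = x$thresholds[[cl]]$p_cutoff,
        n_discoveries = x$thresholds[[cl]]$n_discoveries,
        n_permutations = x$thresholds[[cl]]$n_permutations)
  }
  for (cl in c("cis", "trans"))
    thr_rows[[length(thr_rows) + 1L]] <- data.frame(
      cohort = "meta", class = cl,
      p_cutoff = result$meta$thresholds[[cl]]$p_cutoff,
      n_discoveries = result$meta$thresholds[[cl]]$n_discoveries,
      n_permutations = result$meta$thresholds[[cl]]$n_permutations)
  write_tsv(do.call(rbind, thr_rows), fp("thresholds.tsv"))
  write_tsv(result$meta$calls, fp("eqtl_calls_meta.tsv"))
  mc <- result$meta$calls
  if (nrow(mc) > 0)
    write_tsv(meta_records(result$meta, mc$snp_id, mc$probeset_id),
              fp("meta.tsv"))
  write_tsv(result$replication$records, fp("replication.tsv"))
  write_tsv(result$esnp_set$pairs, fp("esnp_set.tsv"))
  write_tsv(result$links$links, fp("gwas_links.tsv"))
  if (!is.null(result$qq)) {
    write_tsv(result$qq$qq, fp("qq.tsv"))
    jsonlite::write_json(list(enrichment_p = result$qq$enrichment_p),
                         fp("enrichment.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$subnetwork))
    write_tsv(igraph::as_data_frame(result$subnetwork$graph),
              fp("subnetwork.tsv"))
  if (!is.null(result$kda)) write_tsv(result$kda$results, fp("kda.tsv"))
  if (!is.null(result$locus_ranking))
    write_tsv(result$locus_ranking, fp("locus_rank.tsv"))
  jsonlite::write_json(result$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.eqtl_pipeline <- function(x, ...) {
  pipeline_report(x$summary, locus = x$locus_ranking)
  invisible(x)
}

#' Render a run summary as human-readable tables
#'
#' Prints the per-cohort and meta cutoff/count table (one column block per
#' cohort plus the meta) and, when available, the locus-candidate ranking
#' sorted by ascending P.
#'
#' @param summary the `$summary` of an `eqtl_pipeline` (or the same
#'   structure read back from summary.json).
#' @param locus optional `locus_ranking` to print.
#' @return the summary, invisibly.
#' @export
pipeline_report <- function(summary, locus = NULL) {
  if (is.null(summary)) stop("missing run summary")
  rows <- c(summary$cohorts, list(summary$meta))
  tab <- data.frame(
    cohort = vapply(rows, function(r) as.character(r$cohort), ""),
    cis_cutoff = vapply(rows, function(r) as.numeric(r$cis_cutoff), 0),
    cis_eqtls = vapply(rows, function(r) as.integer(r$cis_calls), 0L),
    trans_cutoff = vapply(rows, function(r) as.numeric(r$trans_cutoff), 0),
    trans_eqtls = vapply(rows, function(r) as.integer(r$trans_calls), 0L))
  cat("eQTLs detected at the permutation FDR target\n")
  print(tab, row.names = FALSE, digits = 3)
  cat("\neSNPs:", summary$n_esnps,
      "| GWAS-linked SNPs:", summary$n_gwas_linked_snps,
      "-> unique genes:", summary$n_linked_genes, "\n")
  if (!is.null(summary$enrichment_p) && !is.na(summary$enrichment_p))
    cat("GWAS enrichment P (one-sided Mann-Whitney):",
        format(summary$enrichment_p, digits = 3), "\n")
  cat("Key drivers:", summary$n_key_drivers,
      if (summary$n_key_drivers > 0)
        paste0("( ", paste(summary$key_drivers, collapse = ", "), " )")
      else "", "\n")
  if (!is.null(locus) && nrow(locus) > 0) {
    cat("\nLocus candidate ranking (canonical-gene enrichment)\n")
    print(head(as.data.frame(locus)[, c("gene", "x", "k_draw", "p")], 10),
          row.names = FALSE, digits = 3)
  }
  invisible(summary)
}
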