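# eqtlnet

Multi-cohort lung-style eQTL mapping, cross-cohort meta-analysis, GWAS
integration, and directed-network key-driver analysis — as one tested R
package with a seeded synthetic-data generator for end-to-end calibration.

## The science

Expression quantitative trait loci (eQTLs) are genetic variants associated
with transcript abundance. Mapping them in disease-relevant tissue across
several cohorts, then intersecting them with disease GWAS hits, turns
anonymous associated SNPs into named genes: a GWAS SNP that is also an
eSNP points at the transcripts it controls. Embedding those genes in a
directed gene-regulatory network then ranks candidates at a locus (which
gene sits closest to the canonical disease genes?) and nominates key
drivers (which genes sit upstream of the disease-associated expression
signature?).

`eqtlnet` implements that chain:

1. **Per-cohort eQTL mapping** — genotype QC (call rate ≥ 0.9, exact
   Hardy-Weinberg P ≥ 1e-6), Huber-robust adjustment of expression for
   age, sex, and smoking, an exhaustive additive single-SNP scan,
   cis/trans classification (±1 Mb, inclusive), and permutation-based FDR
   thresholds at 10% with a best-eSNP calling rule.
2. **Meta-analysis** — inverse-variance fixed effects, Cochran's Q,
   DerSimonian-Laird τ², random effects, meta-level permutation FDR, and
   a replication rule (same sign, P ≤ 1e-4, ≥ 2 cohorts).
3. **GWAS integration** — eSNP set construction, one-sided Mann-Whitney
   enrichment of GWAS P-values at eSNPs with Q-Q coordinates, and strict
   P < 0.01 SNP-to-gene translation.
4. **Network stage** — DAG validation, 3-edge neighborhoods, coherent
   subnetwork extraction, hypergeometric key-driver analysis
   (Bonferroni-adjusted), and locus-candidate ranking against a canonical
   disease-gene list.

All statistical primitives (exact HWE test, Huber IRLS, closed-form OLS
scan, permutation FDR, meta-analysis formulas, upper-tail hypergeometric)
are authored in the package and tested against independent oracles
(`lm()`, `MASS::rlm()`, `metafor::rma()`, brute-force enumeration).

## Worked example

```r
library(eqtlnet)

cfg <- pipeline_config(sim = sim_config(n_cohorts = 3, samples_per_cohort = 150,
                                        n_snps = 600, n_probesets = 150,
                                        network_genes = 60, canonical_size = 30,
                                        seed = 74),
                       seed = 74L, n_perm = 3L, gwas_threshold = 0.05)
res <- run_pipeline(cfg)
print(res)
```

```
eQTLs detected at the permutation FDR target
  cohort cis_cutoff cis_eqtls trans_cutoff trans_eqtls
 cohort1   0.000834        43     2.08e-05          11
 cohort2   0.001407        43     8.99e-07           7
 cohort3   0.000935        37     1.96e-05          10
    meta   0.001905        62     6.05e-06          18

eSNPs: 62 | GWAS-linked SNPs: 12 -> unique genes: 13 
GWAS enrichment P (one-sided Mann-Whitney): 0.0255 
Key drivers: 0  

Locus candidate ranking (canonical-gene enrichment)
  gene  x k_draw     p
 G0053 13     24 0.627
 G0041 10     22 0.917
```

Note the meta row: pooling the three cohorts yields more cis-eQTLs (62)
than the best single cohort (43) at the same 10% FDR — the expected gain
from inverse-variance combination.

The locus-ranking operation can also be used directly. For a candidate
gene whose 3-edge network neighborhood holds 130 genes, 7 of them from a
canonical list of 119, against a background universe of 7,119 genes:

```r
edges <- data.frame(parent = "CANDIDATE",
                    child = c(paste0("CANON", 1:7), paste0("OTHER", 1:123)))
net <- load_network(edges)
canonical <- c(paste0("CANON", 1:7), paste0("CANONOFF", 1:112))  # 119 genes
rank_locus_candidates(net, candidates = "CANDIDATE",
                      canonical = canonical, h = 3, background = 7119)
```

```
       gene x k_draw   m    n           p in_network
1 CANDIDATE 7    130 119 7000 0.005935466       TRUE
```

A command-line front end with `simulate`, `run-all`, `kda`, `rank-locus`,
and per-stage subcommands is installed at
`system.file("cli/eqtlnet.R", package = "eqtlnet")`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
model and assumptions, every tuning constant and why it has its default,
the synthetic generator's scope and limits, numerical choices, and known
limitations (small-k bias of the DerSimonian-Laird estimator, the
stand-in structure learner).
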