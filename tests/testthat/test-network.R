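# Network stage: DAG loading and validation, neighborhoods, subnetwork
# extraction, hypergeometric enrichment, key driver analysis, locus
# candidate ranking, and the stand-in structure learner.

chain_net <- function() {
  load_network(data.frame(parent = c("a", "b", "c", "d"),
                          child = c("b", "c", "d", "e")))
}

test_that("load_network validates, uppercases, dedupes, and names cycles", {
  g <- chain_net()
  expect_s3_class(g, "gene_network")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D", "E"))
  expect_identical(igraph::ecount(g), 4)
  expect_true(igraph::is_dag(g))

  # file input with a header row
  f <- tempfile(fileext = ".tsv")
  writeLines(c("parent_gene\tchild_gene", "x\ty", "y\tz"), f)
  gf <- load_network(f)
  expect_setequal(igraph::V(gf)$name, c("X", "Y", "Z"))
  expect_identical(igraph::ecount(gf), 2)

  expect_warning(gd <- load_network(data.frame(p = c("a", "A"),
                                               c = c("b", "b"))),
                 "duplicate")
  expect_identical(igraph::ecount(gd), 1)
  expect_error(load_network(data.frame(p = "a", c = "a")), "self-loop")
  err <- tryCatch(load_network(data.frame(p = c("a", "b", "c"),
                                          c = c("b", "c", "a"))),
                  error = conditionMessage)
  expect_match(err, "cycle")
  expect_match(err, "A")
  expect_error(load_network(data.frame(p = "a")), "two columns")
  expect_output(print(g), "5 genes")
})

test_that("neighborhoods ignore direction and respect the radius exactly", {
  g <- chain_net()
  # undirected breadth-first from B: radius 1 {A, C}, radius 2 adds D
  expect_identical(neighborhood(g, "b", h = 1), c("A", "C"))
  expect_identical(neighborhood(g, "b", h = 2), c("A", "C", "D"))
  expect_identical(neighborhood(g, "b", h = 10), c("A", "C", "D", "E"))
  expect_identical(neighborhood(g, "B", h = 0), character())
  expect_error(neighborhood(g, "zz"), "unknown gene")
})

test_that("subnetwork extraction prefers seed proportion, then size", {
  # two components: P-Q-R (2 seeds of 3 genes) and S-T-U-V-W (1 seed of 5)
  g <- load_network(data.frame(
    p = c("p", "q", "s", "t", "u", "v"),
    c = c("q", "r", "t", "u", "v", "w")))
  sub <- extract_subnetwork(g, seeds = c("p", "r", "s"), h = 3)
  expect_setequal(igraph::V(sub$graph)$name, c("P", "Q", "R"))
  expect_equal(sub$proportion, 2 / 3, tolerance = 1e-12)
  expect_identical(sub$size, 3L)
  expect_identical(nrow(sub$components), 2L)
  # equal proportions (1/2 seeds in both components): the larger wins
  g2 <- load_network(data.frame(p = c("a", "m", "n", "o"),
                                c = c("b", "n", "o", "p")))
  sub2 <- extract_subnetwork(g2, seeds = c("a", "m", "n"), h = 3)
  expect_setequal(igraph::V(sub2$graph)$name, c("M", "N", "O", "P"))
  expect_error(extract_subnetwork(g, seeds = "zz"), "no seed gene")
  expect_output(print(sub), "Coherent subnetwork")
})

test_that("hypergeom_upper matches brute-force enumeration exactly", {
  # exhaustive check over every consistent configuration up to size 25
  for (m in c(2, 5, 9)) for (n in c(3, 7, 16)) {
    for (k in 1:min(12, m + n)) for (x in 0:min(k, m)) {
      expect_equal(hypergeom_upper(x, k, m, n), hyper_upper_enum(x, k, m, n),
                   tolerance = 1e-12,
                   label = sprintf("x=%d k=%d m=%d n=%d", x, k, m, n))
    }
  }
  # worked example: both drawn from 2 successes among 4 in 2 draws
  expect_equal(hypergeom_upper(2, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_identical(hypergeom_upper(0, 5, 3, 10), 1)
  # monotone decreasing in x
  ps <- vapply(0:5, function(x) hypergeom_upper(x, 5, 10, 40), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_upper(3, 2, 5, 5), "x > k")
  expect_error(hypergeom_upper(-1, 2, 5, 5), "negative")
  expect_error(hypergeom_upper(6, 10, 5, 2), "x > m")
})

test_that("key driver analysis scores downstream overlap by hand", {
  # HUB feeds 8 targets; a 5-gene chain of distractors
  g <- load_network(data.frame(
    p = c(rep("hub", 8), "d1", "d2", "d3", "d4"),
    c = c(paste0("t", 1:8), "d2", "d3", "d4", "d5")))
  kda <- key_driver_analysis(g, targets = paste0("t", 1:8), h = 3,
                             alpha = 0.05)
  # 14 nodes, m = 8, n = 6; HUB: x = k = 8 so P = 1/choose(14, 8)
  expect_identical(kda$results$gene[1], "HUB")
  expect_equal(kda$results$p[1], 1 / choose(14, 8), tolerance = 1e-12)
  expect_equal(kda$results$p_adjusted[1], 14 / choose(14, 8),
               tolerance = 1e-12)
  expect_identical(kda$drivers, "HUB")
  # D1 reaches only distractors: x = 0, P = 1
  d1 <- kda$results[kda$results$gene == "D1", ]
  expect_identical(d1$x, 0L)
  expect_equal(d1$p, 1)
  expect_false(d1$driver)
  expect_error(key_driver_analysis(g, targets = "zz"), "no target")
  expect_output(print(kda), "Key driver")
})

test_that("key driver analysis recovers planted hubs in simulated DAGs", {
  hits <- 0L
  for (s in 1:25) {
    net <- simulate_network(small_cfg(seed = s, n_hubs = 1,
                                      hub_children = 10))
    g <- load_network(net$edges[, c("parent_gene", "child_gene")])
    hub <- net$hubs[1]
    targets <- eqtlnet:::downstream(g, hub, 3)
    kda <- key_driver_analysis(g, targets, h = 3)
    if (length(kda$drivers) > 0 && kda$results$gene[1] == hub)
      hits <- hits + 1L
  }
  expect_gte(hits, 23L)
})

test_that("locus ranking scores canonical enrichment with the full list", {
  # star: candidate CAND with 7 neighbors, 3 of them canonical
  g <- load_network(data.frame(
    p = rep("cand", 7), c = c("k1", "k2", "k3", paste0("z", 1:4))))
  canonical <- c("k1", "k2", "k3", paste0("offnet", 1:7))   # m = 10
  rk <- rank_locus_candidates(g, candidates = c("cand", "absent"),
                              canonical = canonical, h = 1,
                              background = 100)
  cand <- rk[rk$gene == "CAND", ]
  expect_identical(cand$x, 3L)
  expect_identical(cand$k_draw, 7L)
  expect_identical(cand$m, 10L)
  expect_equal(cand$n, 90)
  expect_equal(cand$p, hyper_upper_enum(3, 7, 10, 90), tolerance = 1e-12)
  # absent candidates score x = k = 0 with P = 1
  ab <- rk[rk$gene == "ABSENT", ]
  expect_identical(ab$x, 0L)
  expect_equal(ab$p, 1)
  expect_false(ab$in_network)
  # ranked ascending by P
  expect_identical(rk$gene, c("CAND", "ABSENT"))
  # default background = union of network and canonical genes
  rk2 <- rank_locus_candidates(g, "cand", canonical, h = 1)
  expect_identical(rk2$n[1], length(union(igraph::V(g)$name,
                                          toupper(canonical))) - 10L)
  expect_error(rank_locus_candidates(g, "cand", character()), "empty")
  expect_error(rank_locus_candidates(g, "cand", canonical, h = 1,
                                     background = 5), "background")
})

test_that("the stand-in learner recovers a strong chain and stays sparse", {
  recovered <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 200
    a <- rnorm(n); b <- 0.9 * a + rnorm(n, sd = 0.4)
    c_ <- 0.9 * b + rnorm(n, sd = 0.4); d <- 0.9 * c_ + rnorm(n, sd = 0.4)
    X <- rbind(A = a, B = b, C = c_, D = d)
    g <- learn_network_standin(X)
    skel <- igraph::as_edgelist(igraph::as_undirected(g))
    skel <- apply(skel, 1, function(e) paste(sort(e), collapse = "-"))
    if (setequal(skel, c("A-B", "B-C", "C-D"))) recovered <- recovered + 1L
  }
  expect_gte(recovered, 18L)

  # independent noise: the learner adds at most an edge or two
  edges <- vapply(1:20, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(6 * 150), 6, 150,
                dimnames = list(paste0("g", 1:6), NULL))
    igraph::ecount(learn_network_standin(X))
  }, 0)
  expect_lte(max(edges), 2)
  expect_lte(mean(edges), 1)

  expect_error(learn_network_standin(matrix(rnorm(40), 4, 10)),
               "at least 50 samples")
})

test_that("the learner output feeds the downstream network stage", {
  set.seed(61)
  n <- 150
  hub <- rnorm(n)
  X <- rbind(HUB = hub,
             t(vapply(1:6, function(i) 0.8 * hub + rnorm(n, sd = 0.5),
                      numeric(n))))
  rownames(X)[2:7] <- paste0("TGT", 1:6)
  g <- learn_network_standin(X)
  expect_s3_class(g, "gene_network")
  expect_true(igraph::is_dag(g))
  # all targets attach to the hub in the skeleton
  nb <- neighborhood(g, "HUB", h = 1)
  expect_gte(length(intersect(nb, paste0("TGT", 1:6))), 5L)
})
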