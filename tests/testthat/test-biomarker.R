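test_that("local-mean edge filter keeps exactly the locally supported edges", {
  tri <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
                    n_sources = c(5L, 1L, 3L), directed = FALSE)
  kept <- robustify(tri)
  # m(A)=3, m(B)=4, m(C)=2: keep A-B (5>=3) and B-C (3>=2), drop A-C
  expect_equal(nrow(kept), 2)
  expect_setequal(paste(kept$gene_a, kept$gene_b), c("A B", "B C"))

  # equal support everywhere: nothing dropped
  eq <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
                   n_sources = 2L, directed = FALSE)
  expect_equal(robustify(eq), eq)

  # output is a subset and no node is isolated
  set.seed(19)
  pairs <- t(combn(sprintf("N%02d", 1:12), 2))
  take <- runif(nrow(pairs)) < 0.4
  ed <- data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                   n_sources = sample(1:9, sum(take), replace = TRUE),
                   directed = FALSE)
  out <- robustify(ed)
  expect_lte(nrow(out), nrow(ed))
  expect_setequal(unique(c(out$gene_a, out$gene_b)),
                  unique(c(ed$gene_a, ed$gene_b)))
})

test_that("graph statistics reproduce the reference network densities", {
  # the published robust PPI network: 20,260 nodes / 806,250 undirected edges
  ppi <- graph_stats(n_nodes = 20260, n_edges = 806250, directed = FALSE)
  expect_equal(round(ppi$density, 4), 0.0039)
  # the TF-target network: 18,754 nodes / 363,649 directed edges
  tf <- graph_stats(n_nodes = 18754, n_edges = 363649, directed = TRUE)
  expect_equal(round(tf$density, 3), 0.001)
  # complete graph K5
  k5 <- graph_stats(igraph::make_full_graph(5))
  expect_equal(k5$density, 1.0)
  expect_warning(graph_stats(n_nodes = 1, n_edges = 0), "undefined")
})

test_that("centralities match structure on canonical small graphs", {
  star <- data.frame(gene_a = "HUB", gene_b = sprintf("L%d", 1:4))
  g <- edges_to_graph(star, directed = FALSE)
  cp <- centrality_profile(g)
  expect_equal(cp$degree[cp$gene == "HUB"], 4)
  expect_equal(cp$degree[cp$gene == "L1"], 1)
  # center lies on all shortest paths between the 6 leaf pairs
  expect_equal(cp$betweenness[cp$gene == "HUB"], 6)
  expect_equal(cp$betweenness[cp$gene == "L1"], 0)

  path3 <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  cp3 <- centrality_profile(edges_to_graph(path3))
  expect_equal(cp3$betweenness[cp3$gene == "B"], 1)
})

test_that("centralities equal brute-force oracles on small random graphs", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    nodes <- sprintf("V%d", 1:n)
    pairs <- t(combn(nodes, 2))
    take <- runif(nrow(pairs)) < 0.5
    if (sum(take) < n - 1) take[sample.int(nrow(pairs), n)] <- TRUE
    ed <- data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2])
    g <- edges_to_graph(ed, directed = FALSE)
    cp <- centrality_profile(g)
    oracle <- brute_centralities(as.matrix(ed), directed = FALSE)
    idx <- cp$gene
    expect_equal(setNames(cp$degree, idx), oracle$degree[idx])
    expect_equal(setNames(cp$betweenness, idx), oracle$betweenness[idx],
                 tolerance = 1e-10)
    expect_equal(setNames(cp$closeness, idx), oracle$closeness[idx],
                 tolerance = 1e-10)
    # eigenvector centrality: power iteration vs dense eigendecomposition
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    ev <- eigen(adj)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_equal(unname(setNames(cp$eigenvector, idx)[rownames(adj)]), ev,
                 tolerance = 1e-6)
  }
})

test_that("Borda aggregation averages ranks with missing-gene penalty", {
  l1 <- c(a = 1, b = 2, c = 3)
  l2 <- c(c = 1, a = 2, b = 3)
  res <- borda(list(l1, l2))
  expect_equal(res$gene, c("a", "c", "b"))
  expect_equal(res$mean_rank, c(1.5, 2.0, 2.5))

  # identical lists preserve the order; a single list is the identity
  expect_equal(borda(list(l1, l1))$gene, c("a", "b", "c"))
  expect_equal(borda(list(l1))$gene, c("a", "b", "c"))
  expect_error(borda(list()), "empty")

  # permutation invariance (of list order and storage order)
  l3 <- c(b = 1, c = 2, a = 3)
  r_abc <- borda(list(l1, l2, l3))
  r_perm <- borda(list(l3, l1, l2[sample(names(l2))]))
  expect_equal(r_perm, r_abc)

  # a gene missing from one list receives rank n+1 there
  short <- c(a = 1, b = 2)
  res_m <- borda(list(l1, short))
  expect_equal(res_m$mean_rank[res_m$gene == "c"], (3 + 3) / 2)
})

test_that("specificity scores count distinct KE occurrences with Inf first", {
  sets <- c(
    lapply(1:4, function(i) c("SHARED", "TGT_ONLY", sprintf("t%d", i))),
    lapply(1:8, function(i) c("SHARED", sprintf("o%d", i))))
  names(sets) <- c(sprintf("PF%d", 1:4), sprintf("OTH%d", 1:8))
  sp <- specificity(sprintf("PF%d", 1:4), sets)
  expect_equal(sp$score[sp$gene == "SHARED"], 4 / 8)
  expect_equal(sp$score[sp$gene == "TGT_ONLY"], Inf)
  expect_equal(sp$gene[1], "TGT_ONLY")   # infinity ranked first
  # full ranking equals a counting oracle
  for (i in seq_len(nrow(sp))) {
    g <- sp$gene[i]
    expect_equal(sp$n_target[i],
                 sum(vapply(sets[sprintf("PF%d", 1:4)],
                            function(s) g %in% s, logical(1))))
    expect_equal(sp$n_other[i],
                 sum(vapply(sets[sprintf("OTH%d", 1:8)],
                            function(s) g %in% s, logical(1))))
  }
  expect_false("o1" %in% sp$gene)  # genes absent from targets are excluded
})

test_that("the aggregated target rank reduces correctly and is deterministic", {
  # single KE, single network: reduces to the centrality Borda
  ed <- data.frame(gene_a = c("A", "A", "B", "C"),
                   gene_b = c("B", "C", "C", "D"))
  g <- edges_to_graph(ed)
  cp <- centrality_profile(g)
  ke_sets <- list(KE1 = c("A", "B", "C", "D"))
  r1 <- pf_rank(ke_sets, list(cp))
  measures <- c("degree", "betweenness", "closeness", "eigenvector")
  oracle_lists <- lapply(measures, function(m)
    rank_descending(setNames(cp[[m]], cp$gene)))
  expect_equal(r1, borda(list(as_ranklist_oracle = as_ranklist(
    borda(oracle_lists)))))

  # a gene top-ranked in every per-KE list is global rank 1
  ke_sets3 <- list(KE1 = c("A", "B"), KE2 = c("A", "C"), KE3 = c("A", "D"))
  r3 <- pf_rank(ke_sets3, list(cp))
  expect_equal(r3$gene[1], "A")

  # deterministic: two runs are identical
  expect_identical(pf_rank(ke_sets3, list(cp)), r3)
})

test_that("three-KE fixture equals a step-by-step manual Borda chain", {
  cents <- list(
    data.frame(gene = c("A", "B", "C"), degree = c(3, 2, 1),
               betweenness = c(1, 2, 3), closeness = c(3, 2, 1),
               eigenvector = c(3, 2, 1)))
  ke_sets <- list(K1 = c("A", "B"), K2 = c("B", "C"), K3 = c("A", "B", "C"))
  res <- pf_rank(ke_sets, cents)
  # manual chain: per KE, rank genes by each measure among the KE's genes
  manual_ke <- lapply(ke_sets, function(genes) {
    l4 <- lapply(c("degree", "betweenness", "closeness", "eigenvector"),
                 function(m) {
                   v <- setNames(cents[[1]][[m]], cents[[1]]$gene)[genes]
                   rank_descending(v)
                 })
    as_ranklist(borda(l4))
  })
  expect_equal(res, borda(manual_ke))
})

test_that("candidate selection assigns evidence tiers and covers KEs", {
  rank_df <- data.frame(gene = sprintf("g%02d", 1:20), rank = 1:20)
  ev <- data.frame(gene = sprintf("g%02d", 1:20),
                   deg_in_vivo = FALSE, deg_in_vitro = FALSE,
                   dose_dep_in_vivo = FALSE, dose_dep_in_vitro = FALSE)
  ev$deg_in_vivo[1] <- ev$deg_in_vitro[1] <- TRUE
  ev$dose_dep_in_vivo[1] <- TRUE               # tier 1
  ev$deg_in_vitro[2] <- TRUE                   # tier 2
  ev$dose_dep_in_vitro[3] <- TRUE              # tier 3
  sel <- select_candidates(rank_df, ev, top_fraction = 0.2)
  expect_equal(sel$tier[sel$gene == "g01"], "1")
  expect_equal(sel$tier[sel$gene == "g02"], "2")
  expect_equal(sel$tier[sel$gene == "g03"], "3")
  expect_false("g05" %in% sel$gene)            # no evidence, no tier

  # evidence outside the top fraction is not tiered
  ev2 <- ev; ev2$deg_in_vivo[15] <- ev2$deg_in_vitro[15] <- TRUE
  sel2 <- select_candidates(rank_df, ev2, top_fraction = 0.2)
  expect_false("g15" %in% sel2$gene)

  # no evidence at all: empty tiers
  ev0 <- ev; ev0[, -1] <- FALSE
  expect_equal(nrow(select_candidates(rank_df, ev0, top_fraction = 0.2)), 0)

  # the coverage tier admits a lower-ranked gene for an uncovered KE
  ke_sets <- list(KEcov = c("g18"))
  sel3 <- select_candidates(rank_df, ev, ke_sets = ke_sets,
                            top_fraction = 0.2)
  expect_equal(sel3$tier[sel3$gene == "g18"], "coverage")
})
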