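test_that("Fisher enrichment p-values match exhaustive hypergeometric tails", {
  u <- sprintf("g%02d", 1:20)
  s <- u[1:5]
  q <- c(u[1:3], u[6:7])
  row <- fisher_enrich(q, list(S = s), u)
  expect_equal(row$overlap, 3)
  expect_equal(row$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(row$p, hyper_tail_oracle(3, 5, 5, 20), tolerance = 1e-12)

  # random instances with universe <= 30 against full enumeration
  set.seed(21)
  for (i in 1:30) {
    N <- sample(8:30, 1)
    uni <- sprintf("u%02d", 1:N)
    set1 <- sample(uni, sample(1:N, 1))
    query <- sample(uni, sample(1:N, 1))
    got <- fisher_enrich(query, list(A = set1), uni)
    expect_equal(got$p,
                 hyper_tail_oracle(got$overlap, got$set_size,
                                   got$query_size, N),
                 tolerance = 1e-10)
  }
})

test_that("degenerate enrichment inputs behave as defined", {
  u <- sprintf("g%02d", 1:10)
  # query identical to the only set covering the whole draw -> p = 1
  expect_equal(fisher_enrich(u[1:4], list(S = u[1:4]), u[1:4])$p, 1)
  # empty set -> p = 1 row
  expect_equal(fisher_enrich(u[1:3], list(S = character(0)), u)$p, 1)
  # empty query after universe intersection -> error
  expect_error(fisher_enrich("NOT_IN_UNIVERSE", list(S = u[1:3]), u),
               "empty query")
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  # hand case: (0.01, 0.02, 0.03, 0.04) over 4 sets -> all 0.04
  u <- sprintf("g%03d", 1:300)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- p.adjust(p, "BH")            # the path fisher_enrich uses
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(p.adjust(p[perm], "BH"), adj[perm])
  }
})

test_that("pooling comparisons unions the filtered DEG sets", {
  t1 <- data.frame(comparison_id = "c1", gene = c("A", "B", "X"),
                   log2fc = c(2, 1, 0.1), adj_p = c(0.001, 0.001, 0.001))
  t2 <- data.frame(comparison_id = "c2", gene = c("B", "C", "Y"),
                   log2fc = c(-2, 1.5, 2), adj_p = c(0.001, 0.001, 0.9))
  expect_setequal(pool_moa(list(t1, t2)), c("A", "B", "C"))
  expect_setequal(pool_moa(list(t1)), filter_degs(t1))
  # three comparisons, hand-filtered union
  t3 <- data.frame(comparison_id = "c3", gene = c("D", "A"),
                   log2fc = c(1.1, 0.2), adj_p = c(0.01, 0.01))
  expect_setequal(pool_moa(list(t1, t2, t3)), c("A", "B", "C", "D"))
})

test_that("chemical screening ranks the planted pathway and filters sizes", {
  u <- sprintf("g%03d", 1:300)
  aop_sets <- list(AOP1 = u[1:60], AOP2 = u[61:120], AOP3 = u[121:180])
  chems <- list(
    exact = list(chemical_id = "exact", name = "x", genes = u[1:60],
                 category = "cat1"),
    small = list(chemical_id = "small", name = "s", genes = u[1:30],
                 category = "cat1"))
  relevance <- list(AOP1 = "cat1", AOP2 = "cat2", AOP3 = "cat3")
  res <- suppressMessages(
    screen_chemicals(chems, aop_sets, u, relevance = relevance))
  expect_equal(res$excluded, "small")
  top <- res$hits[res$hits$chemical_id == "exact", ]
  expect_equal(top$set_id[1], "AOP1")
  expect_true(res$flags$flagged[res$flags$chemical_id == "exact"])
  expect_equal(res$by_category$prop_flagged[res$by_category$category ==
                                              "cat1"], 1)
})

test_that("planted chemical fixture recovers target pathways for most chemicals", {
  cfg <- fixture_config(seed = 5)
  scaffold <- simulate_aop_structure(cfg)
  sets <- aop_gene_sets(scaffold$aops, scaffold$ke_sets)
  sim <- simulate_chemicals(cfg, sets)
  universe <- gene_pool <- sprintf("G%04d", 1:cfg$gene_pool_size)
  res <- suppressMessages(
    screen_chemicals(sim$chemicals, sets, universe,
                     relevance = sim$relevance))
  expect_gte(mean(res$flags$flagged), 0.8)
  # output invariant to chemical input order
  res2 <- suppressMessages(
    screen_chemicals(rev(sim$chemicals), sets, universe,
                     relevance = sim$relevance))
  expect_equal(res2$hits, res$hits)
})

test_that("fingerprint pass rule matches the coverage and min-2 boundaries", {
  mk_fp <- function(n_total, n_enr, fdr, cut = 0.05) {
    fdr < cut && (n_enr / n_total >= 1 / 3 || (n_total < 6 && n_enr >= 2))
  }
  # the two in-paper coverage cases: 7/8 and 3/8 both pass
  expect_true(mk_fp(8, 7, 0.01))
  expect_true(mk_fp(8, 3, 0.01))
  expect_false(mk_fp(8, 2, 0.01))    # 0.25 < 1/3 and length >= 6
  expect_true(mk_fp(5, 2, 0.01))     # min-2 rule for short AOPs
  expect_false(mk_fp(5, 1, 0.01))
  expect_false(mk_fp(8, 7, 0.06))    # AOP-level FDR gate

  # and through the real pipeline on constructed gene sets:
  # one AOP of 8 KEs, query overlapping 7 of them strongly
  u <- sprintf("g%03d", 1:400)
  ke_sets <- lapply(1:8, function(i) u[((i - 1) * 30 + 1):(i * 30)])
  names(ke_sets) <- sprintf("KE%d", 1:8)
  set.seed(9)
  other <- lapply(1:6, function(i) sample(u, 25))
  names(other) <- sprintf("OKE%d", 1:6)
  aops <- list(
    list(aop_id = "A1", title = "t", ke_ids = names(ke_sets),
         ker_edges = matrix(character(0), ncol = 2), roles = NULL),
    list(aop_id = "A2", title = "t", ke_ids = names(other),
         ker_edges = matrix(character(0), ncol = 2), roles = NULL))
  moa <- unlist(ke_sets[1:7], use.names = FALSE)
  fp <- aop_fingerprint(moa, aops, c(ke_sets, other), universe = u)
  a1 <- fp[fp$aop_id == "A1", ]
  expect_true(a1$pass)
  expect_equal(a1$n_enriched_kes, 7)
  expect_equal(a1$coverage, 7 / 8)
  expect_false(fp$pass[fp$aop_id == "A2"])
})

test_that("flipping a KE group to enriched never turns pass into fail", {
  pass_rule <- function(n_total, n_enr, fdr, cut = 0.05) {
    fdr < cut && (n_enr / n_total >= 1 / 3 || (n_total < 6 && n_enr >= 2))
  }
  for (n_total in 1:10) {
    for (n_enr in 0:(n_total - 1)) {
      for (fdr in c(0.01, 0.2)) {
        before <- pass_rule(n_total, n_enr, fdr)
        after <- pass_rule(n_total, n_enr + 1, fdr)
        expect_true(!before || after)
      }
    }
  }
})

test_that("planted mechanism fingerprint recovers target AOPs, null stays quiet", {
  # collection-scale scaffold: fingerprinting screens a whole pathway
  # collection, so the targets must be a small fraction of the universe
  cfg <- fixture_config(seed = 1, n_aops = 20, gene_pool_size = 2000)
  scaffold <- simulate_aop_structure(cfg)
  sets <- aop_gene_sets(scaffold$aops, scaffold$ke_sets)
  sim <- simulate_moa(cfg, sets, target_aops = names(sets)[1:3])
  moa <- pool_moa(sim$deg_tables)
  fp <- aop_fingerprint(moa, scaffold$aops, scaffold$ke_sets)
  expect_true(all(fp$pass[fp$aop_id %in% sim$truth]))
  # every passing non-target owes its signal to an identical KE gene-set
  # group shared with a target (pathways carrying the same biology)
  groups <- group_identical(scaffold$ke_sets)
  target_groups <- unique(unname(groups$ke_to_group[
    unlist(lapply(scaffold$aops[sim$truth], `[[`, "ke_ids"))]))
  extras <- setdiff(fp$aop_id[fp$pass], sim$truth)
  for (a in extras) {
    g <- unique(unname(groups$ke_to_group[scaffold$aops[[a]]$ke_ids]))
    expect_gte(length(intersect(g, target_groups)), 1)
  }

  # zero planted signal: no pathway passes
  sim0 <- simulate_moa(cfg, sets, target_aops = character(0),
                       signal_fraction = 0)
  moa0 <- pool_moa(sim0$deg_tables)
  fp0 <- aop_fingerprint(moa0, scaffold$aops, scaffold$ke_sets)
  expect_false(any(fp0$pass))
})
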