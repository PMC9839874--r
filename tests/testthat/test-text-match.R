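test_that("preprocessing lowercases, collapses concepts and roots tokens", {
  expect_setequal(preprocess("Positive regulation of EMT, increased."),
                  c("upregulated", "emt", "increase"))
  expect_length(preprocess("the of from in"), 0)
  expect_length(preprocess(""), 0)
  # symbol style unification
  expect_true("ppar-alpha" %in% preprocess("pparalpha agonism"))
  expect_true("ppar-alpha" %in% preprocess("PPAR-alpha agonism"))
  # plural and inflection rooting
  expect_setequal(preprocess("lungs increasing signals"),
                  c("lung", "increase", "signal"))
})

test_that("preprocessing is idempotent on a fixture corpus", {
  texts <- c("Positive regulation of EMT, increased.",
             "Decreased lung fibrosis; PPARalpha signalling!",
             "Cells stopped dividing and bodies formed",
             "activation of macrophages, frustrated phagocytosis")
  for (tx in texts) {
    once <- preprocess(tx)
    twice <- preprocess(paste(once, collapse = " "))
    expect_setequal(twice, once)
  }
})

test_that("IDF weights follow ln(n_docs/df)", {
  corpus <- list(c("common", "rare"), c("common"),
                 c("common", "half"), c("common", "half", "x"))
  idf <- build_idf(corpus)
  expect_equal(unname(idf$idf["common"]), 0)          # in all 4 docs
  expect_equal(unname(idf$idf["half"]), log(2))       # in 2 of 4
  expect_equal(unname(idf$idf["rare"]), log(4))       # in 1 of 4
})

test_that("weighted Jaccard matches the hand-computed example", {
  # 4-document corpus: lung df=1, fibrosis df=2, increase df=4
  corpus <- list(c("lung", "fibrosis", "increase"),
                 c("fibrosis", "increase"),
                 c("increase", "other"),
                 c("increase", "thing"))
  idf <- build_idf(corpus)
  expect_equal(unname(idf$idf["lung"]), log(4))
  expect_equal(unname(idf$idf["fibrosis"]), log(2))
  s <- weighted_jaccard(c("lung", "fibrosis", "increase"),
                        c("fibrosis", "increase"), idf)
  expect_equal(s, log(2) / (log(4) + log(2)), tolerance = 1e-12)
  expect_equal(s, 1 / 3, tolerance = 1e-10)
})

test_that("weighted Jaccard is symmetric, bounded, and degenerates cleanly", {
  set.seed(7)
  vocab <- sprintf("t%02d", 1:30)
  corpus <- replicate(12, sample(vocab, sample(3:8, 1)), simplify = FALSE)
  idf <- build_idf(corpus)
  for (i in 1:25) {
    a <- sample(vocab, sample(1:8, 1))
    b <- sample(vocab, sample(1:8, 1))
    sab <- weighted_jaccard(a, b, idf)
    expect_equal(sab, weighted_jaccard(b, a, idf))
    expect_gte(sab, 0); expect_lte(sab, 1)
  }
  expect_equal(weighted_jaccard(c("t01"), c("t02"), idf), 0)  # disjoint
  idf_pos <- build_idf(list(c("a"), c("b")))                  # all idf equal
  expect_equal(weighted_jaccard(c("a", "b"), c("a"), idf_pos), 0.5)
  expect_equal(weighted_jaccard(character(0), character(0), idf), 0)
})

test_that("weighted Jaccard equals plain Jaccard under uniform weights", {
  set.seed(8)
  vocab <- sprintf("u%02d", 1:20)
  # corpus where every token appears in exactly 1 of 10 docs: idf constant
  corpus <- split(vocab, rep(1:10, each = 2))
  idf <- build_idf(corpus)
  for (i in 1:20) {
    a <- sample(vocab, sample(2:8, 1))
    b <- sample(vocab, sample(2:8, 1))
    plain <- length(intersect(a, b)) / length(union(a, b))
    expect_equal(weighted_jaccard(a, b, idf), plain, tolerance = 1e-12)
  }
})

test_that("candidate ranking is correct, tie-broken, and order-invariant", {
  corpus_terms <- list(
    T01 = c("lung", "fibrosis"), T02 = c("oxidative", "stress"),
    T03 = c("lung", "inflammation"), T04 = c("fibrosis", "liver"),
    T05 = c("stress", "response"), T06 = c("lung", "fibrosis", "chronic"),
    T07 = c("apoptosis"), T08 = c("inflammation", "acute"),
    T09 = c("fibrosis"), T10 = c("lung"))
  ke <- c("lung", "fibrosis")
  idf <- build_idf(c(corpus_terms, list(ke)))
  res <- rank_candidates(ke, corpus_terms, idf, ke_id = "KE1", k = 5)
  # brute-force oracle over all ten terms
  oracle <- vapply(corpus_terms, weighted_jaccard, 0.0, b = ke,
                   idf_model = idf)
  oracle <- sort(oracle[oracle > 0], decreasing = TRUE)
  expect_equal(res$score, unname(oracle[res$term_id]))
  expect_equal(res$score, sort(res$score, decreasing = TRUE))
  expect_equal(res$rank, 1:5)

  # verbatim match ranks first with score 1
  res_exact <- rank_candidates(c("oxidative", "stress"), corpus_terms, idf)
  expect_equal(res_exact$term_id[1], "T02")
  expect_equal(res_exact$score[1], 1.0)

  # equal scores break ties by term_id
  two <- list(TB = c("alpha"), TA = c("alpha"))
  idf2 <- build_idf(c(two, list(c("alpha")), list(c("beta"))))
  r2 <- rank_candidates(c("alpha"), two, idf2, k = 2)
  expect_equal(r2$term_id, c("TA", "TB"))

  # invariant to term input order
  shuffled <- corpus_terms[sample(names(corpus_terms))]
  res_shuf <- rank_candidates(ke, shuffled, idf, ke_id = "KE1", k = 5)
  expect_equal(res_shuf$term_id, res$term_id)

  expect_equal(nrow(rank_candidates(ke, list(), idf)), 0)
})

test_that("KE gene sets assemble by union with ortholog fallback and drop rule", {
  term_genes <- list(T1 = c("A", "B"), T2 = c("B", "C"), T3 = character(0))
  acc <- data.frame(ke_id = "KE1", term_id = c("T1", "T2"),
                    status = c("accepted", "manual"))
  res <- assemble_ke_gene_set("KE1", acc, term_genes)
  expect_setequal(res$genes, c("A", "B", "C"))

  # ortholog fallback for a term with no human genes
  orth <- data.frame(species_gene = c("m1", "m2"), human_gene = c("H1", "H2"))
  acc3 <- data.frame(ke_id = "KE2", term_id = "T3", status = "accepted")
  res3 <- assemble_ke_gene_set("KE2", acc3, term_genes,
                               alt_genes = list(T3 = "m1"), orthologs = orth)
  expect_equal(res3$genes, "H1")

  # all terms empty after fallback -> KE dropped
  res_drop <- assemble_ke_gene_set("KE3", acc3, term_genes)
  expect_null(res_drop)
  built <- build_ke_gene_sets(rbind(acc, acc3), term_genes)
  expect_equal(built$dropped, "KE2")
  expect_named(built$ke_sets, "KE1")

  # unknown term is an integrity error; rejected matches are ignored
  bad <- data.frame(ke_id = "KE1", term_id = "NOPE", status = "accepted")
  expect_error(assemble_ke_gene_set("KE1", bad, term_genes), "integrity")
  rej <- data.frame(ke_id = "KE1", term_id = c("T1", "T2"),
                    status = c("accepted", "rejected"))
  expect_setequal(assemble_ke_gene_set("KE1", rej, term_genes)$genes,
                  c("A", "B"))
})

test_that("planted paraphrase corpus is recovered in the top five", {
  sim <- simulate_corpus(fixture_config(seed = 1))
  cands <- annotate_kes(sim$kes, sim$terms)
  hits <- vapply(seq_len(nrow(sim$truth)), function(i) {
    sim$truth$term_id[i] %in%
      cands$term_id[cands$ke_id == sim$truth$ke_id[i]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # with no paraphrase corruption the true term is always rank 1
  sim0 <- simulate_corpus(fixture_config(seed = 2, paraphrase_noise = 0))
  c0 <- annotate_kes(sim0$kes, sim0$terms)
  top1 <- c0[c0$rank == 1, c("ke_id", "term_id")]
  m <- merge(sim0$truth, top1, by = "ke_id")
  expect_true(all(m$term_id.x == m$term_id.y))
})
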