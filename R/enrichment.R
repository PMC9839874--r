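# Fisher-exact over-representation of gene sets, chemical screening, and
# the AOP fingerprint decision rule.

#' Default gene universe
#'
#' The background for all enrichment tests defaults to the union of genes
#' across the KE gene sets, i.e. the scope of the annotation itself.
#'
#' @param ke_sets named list of KE gene sets.
#' @return character vector of genes.
#' @export
default_universe <- function(ke_sets) {
  sort(unique(unlist(ke_sets, use.names = FALSE)))
}

#' Fisher-exact over-representation test of a query against gene sets
#'
#' One-sided (over-representation) hypergeometric test.  The query and every
#' tested set are intersected with the universe first; the p-value is the
#' upper tail `P(X >= overlap)` with population `|universe|`, successes
#' `|set|` and draws `|query|`.  Benjamini-Hochberg adjustment is applied
#' across all sets tested in the call.
#'
#' @param query character vector of genes.
#' @param sets named list of gene sets.
#' @param universe character vector, the background.
#' @return data.frame with columns `set_id`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, sorted by input set order.
#' @export
fisher_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  q <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    m <- length(s)
    k <- length(intersect(s, query))
    p <- if (m == 0) 1 else
      stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = m, query_size = q,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Screen chemicals against AOP gene sets
#'
#' Each chemical profile (restricted to those with between `min_genes` and
#' `max_genes` associated genes) is tested for over-representation against
#' every AOP gene set.  Per chemical the AOPs significant at
#' `fdr < fdr_cut` are ranked by FDR, then raw p, then `aop_id`, and the
#' top `top_k` retained.  When a map of relevant category labels per AOP is
#' supplied, a chemical is flagged when any of its top AOPs carries the
#' chemical's own category label.
#'
#' @param chemicals named list of chemical profiles (`chemical_id`, `name`,
#'   `genes`, optional `category`).
#' @param aop_sets named list aop_id -> gene set (union of KE genes).
#' @param universe background gene vector.
#' @param fdr_cut significance cut on the adjusted p-value (default 0.01).
#' @param top_k number of top enriched AOPs reported per chemical
#'   (default 5).
#' @param relevance optional named list aop_id -> character vector of
#'   category labels considered relevant for that AOP.
#' @param min_genes,max_genes inclusion bounds on profile size
#'   (defaults 50 and 1000).
#' @return list with `hits` (data.frame of per-chemical top AOPs),
#'   `flags` (data.frame chemical_id, category, flagged),
#'   `by_category` (data.frame category, n, prop_flagged) and
#'   `excluded` (character vector of chemical ids outside the size window).
#' @export
screen_chemicals <- function(chemicals, aop_sets, universe,
                             fdr_cut = 0.01, top_k = 5,
                             relevance = NULL,
                             min_genes = 50, max_genes = 1000) {
  sizes <- vapply(chemicals, function(ch) length(unique(ch$genes)), 0L)
  in_window <- sizes >= min_genes & sizes <= max_genes
  excluded <- vapply(chemicals[!in_window], `[[`, "", "chemical_id")
  if (length(excluded) > 0) {
    message("excluded ", length(excluded),
            " chemical(s) outside the ", min_genes, "-", max_genes,
            " gene window: ", paste(excluded, collapse = ", "))
  }
  chems <- chemicals[in_window]
  # deterministic processing order
  chems <- chems[order(vapply(chems, `[[`, "", "chemical_id"))]
  hit_rows <- list()
  flag_rows <- list()
  for (ch in chems) {
    enr <- fisher_enrich(ch$genes, aop_sets, universe)
    sig <- enr[enr$fdr < fdr_cut, , drop = FALSE]
    sig <- sig[order(sig$fdr, sig$p, sig$set_id), , drop = FALSE]
    top <- utils::head(sig, top_k)
    flagged <- NA
    category <- if (!is.null(ch$category)) ch$category else NA_character_
    if (!is.null(relevance) && !is.na(category)) {
      labels <- unlist(relevance[top$set_id], use.names = FALSE)
      flagged <- category %in% labels
    }
    if (nrow(top) > 0) {
      top$chemical_id <- ch$chemical_id
      top$rank <- seq_len(nrow(top))
      hit_rows[[ch$chemical_id]] <- top
    }
    flag_rows[[ch$chemical_id]] <- data.frame(
      chemical_id = ch$chemical_id, category = category,
      flagged = flagged, stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(set_id = character(0), chemical_id = character(0))
  flags <- do.call(rbind, flag_rows)
  rownames(hits) <- NULL
  rownames(flags) <- NULL
  by_category <- NULL
  if (!is.null(relevance)) {
    tab <- flags[!is.na(flags$category), , drop = FALSE]
    if (nrow(tab) > 0) {
      by_category <- do.call(rbind, lapply(split(tab, tab$category),
        function(b) data.frame(category = b$category[1], n = nrow(b),
                               prop_flagged = mean(b$flagged),
                               stringsAsFactors = FALSE)))
      rownames(by_category) <- NULL
    }
  }
  list(hits = hits, flags = flags, by_category = by_category,
       excluded = unname(excluded))
}

#' Pool differential-expression comparisons into a mechanism-of-action set
#'
#' Applies [filter_degs()] per comparison and unions the survivors across
#' all supplied tables.
#'
#' @param deg_tables list of DEG data.frames (columns `comparison_id`,
#'   `gene`, `log2fc`, `adj_p`), or a single data.frame covering several
#'   comparisons.
#' @param fc_threshold,p_threshold see [filter_degs()].
#' @return character vector: the pooled gene set.
#' @export
pool_moa <- function(deg_tables, fc_threshold = 1.5, p_threshold = 0.05) {
  if (is.data.frame(deg_tables)) deg_tables <- list(deg_tables)
  stopifnot(length(deg_tables) >= 1)
  genes <- lapply(deg_tables, function(tab) {
    unlist(lapply(split(tab, tab$comparison_id), filter_degs,
                  fc_threshold = fc_threshold, p_threshold = p_threshold),
           use.names = FALSE)
  })
  sort(unique(unlist(genes, use.names = FALSE)))
}

#' Compute per-AOP gene sets as the union of their KE gene sets
#'
#' @param aops list of AOP records (with `ke_ids`).
#' @param ke_sets named list ke_id -> gene set.
#' @return named list aop_id -> gene set; AOPs with no annotated KE are
#'   omitted.
#' @export
aop_gene_sets <- function(aops, ke_sets) {
  out <- list()
  for (a in aops) {
    genes <- sort(unique(unlist(ke_sets[intersect(a$ke_ids, names(ke_sets))],
                                use.names = FALSE)))
    if (length(genes) > 0) out[[a$aop_id]] <- genes
  }
  out
}

#' AOP fingerprint of a pooled gene signature
#'
#' Two enrichment passes are run: the query against the AOP-level gene
#' sets (union of each AOP's KE genes), and against the KE-level sets,
#' where KEs carrying identical gene sets are first collapsed into groups
#' so the same set is never tested twice.  Every original KE inherits the
#' enrichment verdict of its group.  An AOP enters the fingerprint
#' (`pass = TRUE`) when the AOP itself is enriched at `fdr < fdr_cut` and
#' at least a third of its annotated KEs are enriched - or, for AOPs with
#' fewer than six KEs, at least two KEs.
#'
#' @param moa character vector: pooled gene signature (e.g. [pool_moa()]).
#' @param aops list of AOP records.
#' @param ke_sets named list ke_id -> gene set.
#' @param universe background genes; defaults to [default_universe()].
#' @param fdr_cut significance cut (default 0.05).
#' @param groups optional KE group table from [group_identical()];
#'   computed from `ke_sets` when omitted.
#' @return data.frame with one row per AOP: `aop_id`, `fdr`, `n_ke_total`,
#'   `n_enriched_kes`, `coverage`, `pass`, sorted by `fdr` ascending.
#'   AOPs with no annotated KEs are excluded.
#' @export
aop_fingerprint <- function(moa, aops, ke_sets,
                            universe = default_universe(ke_sets),
                            fdr_cut = 0.05, groups = NULL) {
  if (is.null(groups)) groups <- group_identical(ke_sets)
  group_sets <- groups$group_sets
  ke_to_group <- groups$ke_to_group

  aop_sets <- aop_gene_sets(aops, ke_sets)
  aop_enr <- fisher_enrich(moa, aop_sets, universe)
  ke_enr <- fisher_enrich(moa, group_sets, universe)
  group_hit <- stats::setNames(ke_enr$fdr < fdr_cut, ke_enr$set_id)

  rows <- list()
  for (a in aops) {
    kids <- intersect(a$ke_ids, names(ke_sets))
    if (length(kids) == 0) {
      message("AOP ", a$aop_id, " has no annotated KEs; excluded")
      next
    }
    n_total <- length(kids)
    enriched <- vapply(kids, function(k) isTRUE(group_hit[[ke_to_group[[k]]]]),
                       logical(1))
    n_enr <- sum(enriched)
    coverage <- n_enr / n_total
    fdr <- aop_enr$fdr[aop_enr$set_id == a$aop_id]
    pass <- fdr < fdr_cut &&
      (coverage >= 1 / 3 || (n_total < 6 && n_enr >= 2))
    rows[[a$aop_id]] <- data.frame(
      aop_id = a$aop_id, fdr = fdr, n_ke_total = n_total,
      n_enriched_kes = n_enr, coverage = coverage, pass = pass,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$fdr, out$aop_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
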