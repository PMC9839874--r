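# Robust network construction, centrality profiling, Borda rank
# aggregation, specificity scoring and tiered biomarker selection.

#' Local-mean source-count edge filter
#'
#' For every node the arithmetic mean of the source counts over its
#' incident edges is computed; an edge is retained when its own source
#' count reaches that mean for at least one of its endpoints
#' (`n_sources >= mean(u)` OR `n_sources >= mean(v)`, inclusive).  The
#' comparison is done in integer arithmetic (`n * degree >= sum`), so no
#' floating-point tie ambiguity arises.  Since a node's best-supported
#' edge always reaches its own mean, no node is isolated by the filter.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `n_sources`
#'   (undirected; see [read_edge_table()]).
#' @return the filtered subset of `edges`.
#' @export
robustify <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  s <- as.numeric(edges$n_sources)
  sum_v <- stats::setNames(numeric(length(nodes)), nodes)
  deg_v <- stats::setNames(numeric(length(nodes)), nodes)
  for (col in c("gene_a", "gene_b")) {
    t_s <- tapply(s, edges[[col]], sum)
    t_d <- tapply(rep(1, nrow(edges)), edges[[col]], sum)
    sum_v[names(t_s)] <- sum_v[names(t_s)] + t_s
    deg_v[names(t_d)] <- deg_v[names(t_d)] + t_d
  }
  keep <- s * deg_v[edges$gene_a] >= sum_v[edges$gene_a] |
    s * deg_v[edges$gene_b] >= sum_v[edges$gene_b]
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an igraph network from an edge table
#'
#' @param edges data.frame with `gene_a`, `gene_b` columns.
#' @param directed logical.
#' @return igraph object (simple graph; duplicate edges collapsed).
#' @export
edges_to_graph <- function(edges, directed = FALSE) {
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b"), drop = FALSE], directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Node/edge counts and density of a network
#'
#' Density is `E / (N (N - 1))` for directed networks and
#' `2 E / (N (N - 1))` for undirected ones.
#'
#' @param g an igraph object, or `NULL` when raw counts are given.
#' @param n_nodes,n_edges raw counts (used when `g` is `NULL`).
#' @param directed logical; taken from `g` when supplied.
#' @return list with `n_nodes`, `n_edges`, `density`.
#' @export
graph_stats <- function(g = NULL, n_nodes = NULL, n_edges = NULL,
                        directed = FALSE) {
  if (!is.null(g)) {
    n_nodes <- igraph::vcount(g)
    n_edges <- igraph::ecount(g)
    directed <- igraph::is_directed(g)
  }
  if (n_nodes < 2) {
    warning("density undefined for fewer than 2 nodes; reporting 0")
    density <- 0
  } else {
    density <- n_edges / (n_nodes * (n_nodes - 1))
    if (!directed) density <- 2 * density
  }
  list(n_nodes = n_nodes, n_edges = n_edges, density = density)
}

eigenvector_power <- function(adj, tol = 1e-10, max_iter = 1000) {
  n <- nrow(adj)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    # left eigenvector: a node inherits the scores of its in-neighbours
    x_new <- as.numeric(crossprod(adj, x))
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(NULL)
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) {
      x_new <- x_new / max(x_new)
      names(x_new) <- rownames(adj)
      return(x_new)
    }
    x <- x_new
  }
  NULL
}

#' Centrality profile of a network
#'
#' Computes degree, betweenness, closeness and eigenvector centrality for
#' every node.  On directed networks the degree is in+out, betweenness and
#' closeness follow edge direction, and eigenvector centrality is obtained
#' by deterministic power iteration on the directed adjacency (uniform
#' start, tolerance 1e-10, at most 1000 iterations) with a fallback to the
#' undirected view if the iteration fails to converge.  Closeness on
#' disconnected graphs uses the Wasserman-Faust variant: computed within
#' each node's reachable set and scaled by `(reachable - 1) / (N - 1)`.
#'
#' @param g an igraph network.
#' @return data.frame with columns `gene`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`.
#' @export
centrality_profile <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  directed <- igraph::is_directed(g)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  deg <- igraph::degree(g, mode = "all")
  btw <- igraph::betweenness(g, directed = directed)
  d <- igraph::distances(g, mode = "out")
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0 || n < 2) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0.0)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  eig <- eigenvector_power(adj)
  if (is.null(eig)) {
    message("eigenvector power iteration did not converge on the directed ",
            "adjacency; falling back to the undirected view")
    gu <- igraph::as_undirected(g, mode = "collapse")
    eig <- eigenvector_power(
      as.matrix(igraph::as_adjacency_matrix(gu, sparse = FALSE)))
    if (is.null(eig)) eig <- stats::setNames(rep(0, n), nodes)
  }
  data.frame(gene = nodes, degree = as.numeric(deg[nodes]),
             betweenness = as.numeric(btw[nodes]),
             closeness = clo,
             eigenvector = as.numeric(eig[nodes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank a vector of scores, most central first
#'
#' Ties share the mean rank.
#'
#' @param scores named numeric vector (higher = more central).
#' @return named numeric vector of ranks.
#' @export
rank_descending <- function(scores) {
  r <- rank(-scores, ties.method = "average")
  stats::setNames(as.numeric(r), names(scores))
}

#' Borda rank aggregation
#'
#' Combines rank lists by the arithmetic mean of per-list ranks.  A gene
#' missing from a list is assigned rank `n + 1` in that list, where `n`
#' is the list's length.  The output is sorted ascending by mean rank with
#' ties broken by gene symbol, and re-ranked 1..n with ties sharing the
#' mean rank.
#'
#' @param lists non-empty list of named numeric rank vectors.
#' @return data.frame with columns `gene`, `mean_rank`, `rank`, sorted by
#'   aggregated rank.
#' @export
borda <- function(lists) {
  if (length(lists) == 0) stop("empty input: no rank lists", call. = FALSE)
  genes <- sort(unique(unlist(lapply(lists, names), use.names = FALSE)))
  mat <- vapply(lists, function(l) {
    r <- l[genes]
    r[is.na(r)] <- length(l) + 1
    as.numeric(r)
  }, numeric(length(genes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(genes))
  mean_rank <- rowMeans(mat)
  ord <- order(mean_rank, genes)
  out <- data.frame(gene = genes[ord], mean_rank = mean_rank[ord],
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$mean_rank, ties.method = "average")
  out
}

as_ranklist <- function(borda_out) {
  stats::setNames(borda_out$rank, borda_out$gene)
}

#' Specificity score of genes for a target set of KEs (or AOPs)
#'
#' For each gene, `n_target` counts the distinct target KEs whose gene set
#' contains it and `n_other` the distinct non-target KEs; the score is
#' `n_target / n_other`, infinite when the gene never occurs outside the
#' target.  Ranking: score descending with infinity first, ties by
#' `n_target` descending then gene symbol.  The same function serves the
#' AOP level by passing AOP gene sets.
#'
#' @param target_ids character vector of target KE (or AOP) ids.
#' @param sets named list id -> gene set covering targets and others.
#' @return data.frame with columns `gene`, `n_target`, `n_other`, `score`,
#'   `rank`, restricted to genes occurring in the target sets.
#' @export
specificity <- function(target_ids, sets) {
  target_ids <- intersect(target_ids, names(sets))
  other_ids <- setdiff(names(sets), target_ids)
  genes <- sort(unique(unlist(sets[target_ids], use.names = FALSE)))
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), n_target = integer(0),
                      n_other = integer(0), score = numeric(0),
                      rank = numeric(0)))
  }
  count_in <- function(ids) {
    tab <- table(unlist(lapply(sets[ids], unique), use.names = FALSE))
    out <- stats::setNames(integer(length(genes)), genes)
    hit <- intersect(names(tab), genes)
    out[hit] <- as.integer(tab[hit])
    out
  }
  n_target <- count_in(target_ids)
  n_other <- count_in(other_ids)
  score <- ifelse(n_other == 0, Inf, n_target / n_other)
  ord <- order(-score, -n_target, genes)
  out <- data.frame(gene = genes[ord], n_target = as.integer(n_target[ord]),
                    n_other = as.integer(n_other[ord]),
                    score = score[ord], stringsAsFactors = FALSE)
  # ties share the mean rank; a tie requires equal score AND equal n_target
  grp <- cumsum(!duplicated(data.frame(out$score, out$n_target)))
  out$rank <- stats::ave(seq_len(nrow(out)), grp, FUN = mean)
  rownames(out) <- NULL
  out
}

rerank_within <- function(ranklist, genes) {
  r <- ranklist[intersect(names(ranklist), genes)]
  if (length(r) == 0) return(stats::setNames(numeric(0), character(0)))
  rank_descending(-r)
}

#' Aggregate centralities and specificity into one target rank
#'
#' Per target KE: the KE's genes are ranked by each of the four centrality
#' measures within each network (genes absent from a network share the
#' worst rank plus one), the four lists are Borda-combined per network and
#' the per-network results Borda-combined across networks.  The resulting
#' per-KE centrality rank is then Borda-combined with the KE-level and
#' AOP-level specificity ranks (restricted to the KE's genes).  A final
#' Borda round across the target KEs' lists produces the global rank;
#' genes absent from a KE list receive that list's worst rank plus one.
#'
#' @param target_ke_sets named list ke_id -> gene set for the target KEs.
#' @param centralities list of centrality profiles
#'   (from [centrality_profile()]), one per network.
#' @param spec_ranks list of named rank vectors (e.g. KE-level and
#'   AOP-level specificity ranks from [specificity()]).
#' @return data.frame as returned by [borda()]: the final gene ranking.
#' @export
pf_rank <- function(target_ke_sets, centralities, spec_ranks = list()) {
  measure_cols <- c("degree", "betweenness", "closeness", "eigenvector")
  per_ke <- lapply(names(target_ke_sets), function(kid) {
    genes <- sort(unique(target_ke_sets[[kid]]))
    net_lists <- lapply(centralities, function(cp) {
      idx <- match(genes, cp$gene)
      present <- !is.na(idx)
      lists4 <- lapply(measure_cols, function(mc) {
        vals <- cp[[mc]][idx[present]]
        r <- rank_descending(stats::setNames(vals, genes[present]))
        if (any(!present)) {
          worst <- stats::setNames(rep(sum(present) + 1, sum(!present)),
                                   genes[!present])
          r <- c(r, worst)
        }
        r[genes]
      })
      as_ranklist(borda(lists4))
    })
    cent_rank <- as_ranklist(borda(net_lists))
    if (length(spec_ranks) > 0) {
      spec_local <- lapply(spec_ranks, rerank_within, genes = genes)
      cent_rank <- as_ranklist(borda(c(list(cent_rank), spec_local)))
    }
    cent_rank
  })
  names(per_ke) <- names(target_ke_sets)
  borda(per_ke)
}

#' Tiered selection of candidate biomarkers
#'
#' Genes in the top fraction of the global rank are assigned evidence
#' tiers: tier 1, deregulated both in vivo and in vitro; tier 2,
#' deregulated in vitro only; tier 3, not differentially expressed but
#' dose-dependent.  Within each tier, dose-dependent genes come first,
#' then global rank.  A trailing "coverage" tier admits, for every target
#' KE not covered by the tiered selection, the best-ranked remaining gene
#' belonging to that KE's set.
#'
#' @param rank_df final ranking from [pf_rank()] (columns `gene`, `rank`).
#' @param evidence data.frame with columns `gene`, `deg_in_vivo`,
#'   `deg_in_vitro`, `dose_dep_in_vivo`, `dose_dep_in_vitro` (logicals).
#' @param ke_sets named list ke_id -> gene set of the target KEs (used for
#'   the coverage tier); optional.
#' @param top_fraction fraction of the ranking eligible for tiers
#'   (default 0.10).
#' @return data.frame with columns `gene`, `rank`, `tier` (integer 1-3,
#'   `"coverage"`, or `NA`), ordered by tier then rank.
#' @export
select_candidates <- function(rank_df, evidence, ke_sets = NULL,
                              top_fraction = 0.10) {
  ev <- evidence[match(rank_df$gene, evidence$gene), , drop = FALSE]
  for (col in c("deg_in_vivo", "deg_in_vitro",
                "dose_dep_in_vivo", "dose_dep_in_vitro")) {
    if (is.null(ev[[col]])) ev[[col]] <- FALSE
    ev[[col]][is.na(ev[[col]])] <- FALSE
  }
  dose_dep <- ev$dose_dep_in_vivo | ev$dose_dep_in_vitro
  tier <- rep(NA_character_, nrow(rank_df))
  tier[!ev$deg_in_vivo & !ev$deg_in_vitro & dose_dep] <- "3"
  tier[ev$deg_in_vitro & !ev$deg_in_vivo] <- "2"
  tier[ev$deg_in_vivo & ev$deg_in_vitro] <- "1"
  n_top <- max(1L, ceiling(top_fraction * nrow(rank_df)))
  in_top <- rank_df$rank <= n_top
  tier[!in_top] <- NA_character_
  out <- data.frame(gene = rank_df$gene, rank = rank_df$rank, tier = tier,
                    dose_dependent = dose_dep, stringsAsFactors = FALSE)
  selected <- out[!is.na(out$tier), , drop = FALSE]
  selected <- selected[order(selected$tier, !selected$dose_dependent,
                             selected$rank), , drop = FALSE]
  if (!is.null(ke_sets)) {
    covered <- vapply(ke_sets, function(g) any(selected$gene %in% g),
                      logical(1))
    for (kid in names(ke_sets)[!covered]) {
      pool <- out[is.na(out$tier) & out$gene %in% ke_sets[[kid]], ,
                  drop = FALSE]
      if (nrow(pool) > 0) {
        pick <- pool[which.min(pool$rank), , drop = FALSE]
        pick$tier <- "coverage"
        selected <- rbind(selected, pick)
        out$tier[out$gene == pick$gene] <- "coverage"
      }
    }
  }
  rownames(selected) <- NULL
  selected
}
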