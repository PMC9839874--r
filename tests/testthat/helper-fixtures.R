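# Shared in-code fixtures: a tiny two-pathway scaffold written as the TSV
# files the readers expect, and small utility builders.

write_tiny_scaffold <- function(dir) {
  kes <- data.frame(
    ke_id = c("Event:1", "Event:2", "Event:3", "Event:4", "Event:5"),
    title = c("receptor activation", "oxidative stress", "inflammation",
              "tissue damage", "fibrosis"),
    description = c("activation of the receptor", "increase in oxidative stress",
                    "increased inflammation", "damage to the tissue",
                    "fibrosis of the lung"))
  aops <- data.frame(
    aop_id = c(rep("Aop:A", 3), rep("Aop:B", 4)),
    title = c(rep("pathway A", 3), rep("pathway B", 4)),
    ke_id = c("Event:1", "Event:2", "Event:5",
              "Event:1", "Event:3", "Event:4", "Event:5"),
    position = c(1:3, 1:4),
    role = c("MIE", "KE", "AO", "MIE", "KE", "KE", "AO"))
  ker <- data.frame(
    aop_id = c("Aop:A", "Aop:A", "Aop:B", "Aop:B", "Aop:B"),
    upstream_ke = c("Event:1", "Event:2", "Event:1", "Event:3", "Event:4"),
    downstream_ke = c("Event:2", "Event:5", "Event:3", "Event:4", "Event:5"))
  paths <- list(aops = file.path(dir, "aops.tsv"),
                kes = file.path(dir, "kes.tsv"),
                ker = file.path(dir, "ker.tsv"))
  write.table(aops, paths$aops, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(kes, paths$kes, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ker, paths$ker, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# exhaustive hypergeometric upper-tail oracle by direct enumeration
hyper_tail_oracle <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(vapply(ks, function(k) {
    choose(set_size, k) * choose(universe_size - set_size, query_size - k)
  }, 0.0)) / choose(universe_size, query_size)
}

# Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force betweenness/closeness via BFS path enumeration (small graphs)
brute_centralities <- function(edges, directed = FALSE) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    if (!directed) adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  # all shortest paths between every ordered pair by BFS with predecessor sets
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  nsp <- matrix(0, n, n, dimnames = list(nodes, nodes))   # number of shortest paths
  through <- array(0, c(n, n, n), dimnames = list(nodes, nodes, nodes))
  for (s in seq_len(n)) {
    # enumerate all simple paths from s (tiny graphs only)
    paths <- list(list(s))
    all_paths <- list()
    while (length(paths) > 0) {
      new_paths <- list()
      for (p in paths) {
        last <- p[[length(p)]]
        for (t in seq_len(n)) {
          if (adj[last, t] && !(t %in% unlist(p))) {
            np <- c(p, list(t))
            all_paths[[length(all_paths) + 1]] <- np
            new_paths[[length(new_paths) + 1]] <- np
          }
        }
      }
      paths <- new_paths
    }
    for (p in all_paths) {
      t <- p[[length(p)]]
      len <- length(p) - 1
      if (len < dist[s, t]) {
        dist[s, t] <- len
        nsp[s, t] <- 0
        through[s, t, ] <- 0
      }
      if (len == dist[s, t]) {
        nsp[s, t] <- nsp[s, t] + 1
        mids <- unlist(p)[-c(1, length(p))]
        for (m in mids) through[s, t, m] <- through[s, t, m] + 1
      }
    }
    dist[s, s] <- 0
  }
  btw <- numeric(n)
  names(btw) <- nodes
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || nsp[s, t] == 0) next
    btw <- btw + through[s, t, ] / nsp[s, t]
  }
  if (!directed) btw <- btw / 2
  clo <- vapply(seq_len(n), function(i) {
    di <- dist[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0.0)
  names(clo) <- nodes
  deg <- rowSums(adj) + if (directed) colSums(adj) else 0
  if (!directed) deg <- rowSums(adj)
  list(betweenness = btw, closeness = clo, degree = deg)
}
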