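# Gene-set similarity between KEs, grouping of identical sets, AOP network
# construction, redundant-node merging and GraphML export.

#' Pairwise Jaccard similarity matrix between KE gene sets
#'
#' `JI(A, B) = |A intersect B| / |A union B|`.
#'
#' @param ke_sets named list ke_id -> non-empty gene set.
#' @return symmetric numeric matrix with unit diagonal, dimnames = ke ids.
#' @export
jaccard_matrix <- function(ke_sets) {
  if (any(lengths(ke_sets) == 0)) {
    stop("empty gene set: KEs without genes must be dropped upstream",
         call. = FALSE)
  }
  ids <- names(ke_sets)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2) return(m)
  sets <- lapply(ke_sets, unique)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ji <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      m[i, j] <- ji
      m[j, i] <- ji
    }
  }
  m
}

#' Group key events with identical gene sets
#'
#' Two KEs share a group iff their gene sets are equal (Jaccard index 1).
#' The default path hashes the sorted gene sets; an equivalent
#' complete-linkage path (`method = "hclust"`) converts the similarity
#' matrix to a distance, clusters with complete linkage and cuts at height
#' zero - set equality being transitive, both produce the same partition.
#' The group id is the lexicographically smallest member ke_id.
#'
#' @param ke_sets named list ke_id -> gene set.
#' @param method `"hash"` (default) or `"hclust"`.
#' @return list with `ke_to_group` (named character vector ke_id ->
#'   group_id), `group_sets` (named list group_id -> representative gene
#'   set) and `groups` (named list group_id -> member ke_ids).
#' @export
group_identical <- function(ke_sets, method = c("hash", "hclust")) {
  method <- match.arg(method)
  ids <- names(ke_sets)
  if (method == "hash") {
    keys <- vapply(ke_sets, function(g) paste(sort(unique(g)), collapse = "\r"),
                   "")
    members <- split(ids, keys)
  } else {
    if (length(ids) == 1) {
      members <- list(ids)
    } else {
      sim <- jaccard_matrix(ke_sets)
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
      cl <- stats::cutree(hc, h = 1e-9)
      members <- split(ids, cl)
    }
  }
  group_ids <- vapply(members, function(m) min(m), "")
  names(members) <- group_ids
  members <- members[order(group_ids)]
  ke_to_group <- stats::setNames(
    rep(names(members), lengths(members)),
    unlist(members, use.names = FALSE))
  group_sets <- lapply(names(members), function(g) sort(unique(ke_sets[[g]])))
  names(group_sets) <- names(members)
  list(ke_to_group = ke_to_group[ids], group_sets = group_sets,
       groups = members)
}

#' Build the (unmerged) AOP graph
#'
#' One node per distinct ke_id across the selected AOPs; directed edges
#' from the KER records.  Parallel edges contributed by different AOPs are
#' collapsed into one edge carrying the supporting AOP ids as an
#' attribute.  Node attributes record the member AOPs (nodes with two or
#' more are the "shared" KEs) and the KE role.
#'
#' @param aops list of AOP records (optionally filtered to a subnetwork).
#' @param kes named list of KE records (for roles); optional.
#' @return an [igraph::igraph] directed graph with vertex attributes
#'   `aop_ids` (comma-joined), `role`, and edge attribute `aop_ids`.
#' @export
build_aop_graph <- function(aops, kes = NULL) {
  node_aops <- list()
  roles <- character(0)
  edge_key <- character(0)
  edge_aops <- list()
  for (a in aops) {
    for (k in a$ke_ids) {
      node_aops[[k]] <- union(node_aops[[k]], a$aop_id)
      role <- unname(a$roles[k])
      if (!is.na(role) && (is.na(roles[k]) || !nzchar(roles[k]) ||
                           length(roles[k]) == 0)) {
        roles[k] <- role
      }
    }
    if (nrow(a$ker_edges) > 0) {
      for (i in seq_len(nrow(a$ker_edges))) {
        key <- paste(a$ker_edges[i, 1], a$ker_edges[i, 2], sep = "\r")
        edge_aops[[key]] <- union(edge_aops[[key]], a$aop_id)
      }
    }
  }
  nodes <- sort(names(node_aops))
  ekeys <- names(edge_aops)
  ends <- do.call(rbind, strsplit(ekeys, "\r", fixed = TRUE))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(ends)) {
    g <- igraph::add_edges(g, as.vector(t(ends)))
    igraph::E(g)$aop_ids <- vapply(
      ekeys, function(k) paste(sort(edge_aops[[k]]), collapse = ","), "")
  }
  igraph::V(g)$aop_ids <- vapply(
    nodes, function(k) paste(sort(node_aops[[k]]), collapse = ","), "")
  igraph::V(g)$role <- vapply(nodes, function(k) {
    r <- if (!is.null(kes) && !is.null(kes[[k]])) kes[[k]]$role else roles[k]
    if (is.null(r) || is.na(r)) "KE" else r
  }, "")
  g
}

#' Merge redundant nodes of an AOP graph by KE group
#'
#' Nodes whose KEs carry identical gene sets (same group id) are collapsed
#' into one node named by the group id; attributes are unioned, self-loops
#' dropped and parallel edges collapsed.  The containment report lists
#' every AOP whose merged node and edge sets are a subset of the union of
#' the other AOPs' - AOPs made fully redundant by the merging.
#'
#' @param g graph from [build_aop_graph()].
#' @param groups group table from [group_identical()]; every node of `g`
#'   must have a group.
#' @param aops the AOP records used to build `g` (needed for the
#'   containment report); optional.
#' @return list with `graph` (merged igraph) and `contained`
#'   (character vector of fully contained aop_ids; empty when `aops` is
#'   omitted).
#' @export
merge_graph <- function(g, groups, aops = NULL) {
  nodes <- igraph::V(g)$name
  gid <- groups$ke_to_group[nodes]
  if (any(is.na(gid))) {
    stop("integrity error: node(s) without a group: ",
         paste(nodes[is.na(gid)], collapse = ", "), call. = FALSE)
  }
  ugid <- sort(unique(gid))
  memb <- match(gid, ugid)
  merged <- igraph::contract(g, memb, vertex.attr.comb = list(
    aop_ids = function(x) paste(sort(unique(unlist(strsplit(x, ",")))),
                                collapse = ","),
    role = function(x) x[1],
    name = function(x) NA_character_))
  igraph::V(merged)$name <- ugid
  igraph::V(merged)$group_id <- ugid
  merged <- igraph::simplify(merged, remove.multiple = TRUE,
                             remove.loops = TRUE,
                             edge.attr.comb = list(
    aop_ids = function(x) paste(sort(unique(unlist(strsplit(x, ",")))),
                                collapse = ",")))
  contained <- character(0)
  if (!is.null(aops) && length(aops) > 1) {
    per_aop <- lapply(aops, function(a) {
      nset <- unique(unname(groups$ke_to_group[a$ke_ids]))
      eset <- character(0)
      if (nrow(a$ker_edges) > 0) {
        u <- groups$ke_to_group[a$ker_edges[, 1]]
        v <- groups$ke_to_group[a$ker_edges[, 2]]
        keep <- u != v           # self-loops disappear in the merged graph
        eset <- unique(paste(u[keep], v[keep], sep = "\r"))
      }
      list(aop_id = a$aop_id, nodes = nset, edges = eset)
    })
    for (i in seq_along(per_aop)) {
      others_n <- unique(unlist(lapply(per_aop[-i], `[[`, "nodes")))
      others_e <- unique(unlist(lapply(per_aop[-i], `[[`, "edges")))
      if (all(per_aop[[i]]$nodes %in% others_n) &&
          all(per_aop[[i]]$edges %in% others_e)) {
        contained <- c(contained, per_aop[[i]]$aop_id)
      }
    }
  }
  list(graph = merged, contained = contained)
}

#' Export a graph to GraphML
#'
#' @param g an igraph object.
#' @param path output file path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
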