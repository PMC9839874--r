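# All tabular inputs share one dialect: UTF-8, tab-separated, mandatory header
# row, empty string = missing.  read_table_strict() enforces the header
# contract so downstream code can assume columns exist.

read_table_strict <- function(path, required, sep = "\t") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

write_table_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read AOP scaffold tables
#'
#' Reads the three tab-separated tables describing adverse outcome pathways:
#' `kes.tsv` (columns `ke_id`, `title`, `description`), `aops.tsv`
#' (`aop_id`, `title`, `ke_id`, `position`, `role`) with one row per
#' AOP--KE membership pair, and `ker.tsv` (`aop_id`, `upstream_ke`,
#' `downstream_ke`) with the directed key event relationships.
#'
#' Every cross reference is validated: an AOP membership row or a KER edge
#' that names an unknown `ke_id` raises an integrity error.
#'
#' @param aops_path path to the AOP membership table.
#' @param kes_path path to the key event table.
#' @param ker_path path to the key event relationship table (optional;
#'   `NULL` for AOPs without explicit edges).
#' @return A list with elements `aops` (named list of AOP records, each a
#'   list with `aop_id`, `title`, `ke_ids` in position order, `ker_edges` a
#'   two-column matrix of upstream/downstream ke_ids, and `roles` named by
#'   ke_id) and `kes` (named list of key event records with `ke_id`,
#'   `title`, `description`, `role`).
#' @export
read_aop_tables <- function(aops_path, kes_path, ker_path = NULL) {
  ke_df <- read_table_strict(kes_path, c("ke_id", "title", "description"))
  if (anyDuplicated(ke_df$ke_id)) {
    stop("integrity error: duplicated ke_id in ", basename(kes_path),
         call. = FALSE)
  }
  if (any(!nzchar(ke_df$title))) {
    stop("integrity error: empty KE title in ", basename(kes_path),
         call. = FALSE)
  }
  kes <- lapply(seq_len(nrow(ke_df)), function(i) {
    list(ke_id = ke_df$ke_id[i], title = ke_df$title[i],
         description = ke_df$description[i], role = NA_character_)
  })
  names(kes) <- ke_df$ke_id

  aop_df <- read_table_strict(aops_path,
                              c("aop_id", "title", "ke_id", "position", "role"))
  unknown <- setdiff(aop_df$ke_id, ke_df$ke_id)
  if (length(unknown) > 0) {
    stop("integrity error: AOP table references unknown ke_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(aop_df$role), c("MIE", "KE", "AO"))
  if (length(bad_role) > 0) {
    stop("format error: role must be one of MIE/KE/AO, got: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }

  ker_df <- NULL
  if (!is.null(ker_path)) {
    ker_df <- read_table_strict(ker_path,
                                c("aop_id", "upstream_ke", "downstream_ke"))
    unknown <- setdiff(c(ker_df$upstream_ke, ker_df$downstream_ke), ke_df$ke_id)
    if (length(unknown) > 0) {
      stop("integrity error: KER table references unknown ke_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  aops <- lapply(split(aop_df, aop_df$aop_id), function(block) {
    block <- block[order(as.numeric(block$position)), , drop = FALSE]
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("upstream_ke", "downstream_ke")))
    if (!is.null(ker_df)) {
      kb <- ker_df[ker_df$aop_id == block$aop_id[1], , drop = FALSE]
      if (nrow(kb) > 0) {
        out_of_aop <- setdiff(c(kb$upstream_ke, kb$downstream_ke), block$ke_id)
        if (length(out_of_aop) > 0) {
          stop("integrity error: KER edge of ", block$aop_id[1],
               " uses KE(s) not in that AOP: ",
               paste(out_of_aop, collapse = ", "), call. = FALSE)
        }
        edges <- as.matrix(kb[, c("upstream_ke", "downstream_ke")])
        dimnames(edges) <- list(NULL, c("upstream_ke", "downstream_ke"))
      }
    }
    roles <- block$role
    names(roles) <- block$ke_id
    list(aop_id = block$aop_id[1], title = block$title[1],
         ke_ids = block$ke_id, ker_edges = edges, roles = roles)
  })

  # KE node roles: take the role most often assigned across AOPs
  for (a in aops) {
    for (k in a$ke_ids) {
      if (is.na(kes[[k]]$role)) kes[[k]]$role <- unname(a$roles[[k]])
    }
  }
  list(aops = aops, kes = kes)
}

#' Write AOP scaffold tables
#'
#' Inverse of [read_aop_tables()]; the written files read back to
#' identical records.
#'
#' @param aops,kes as returned by [read_aop_tables()].
#' @param aops_path,kes_path,ker_path output paths.
#' @export
write_aop_tables <- function(aops, kes, aops_path, kes_path, ker_path) {
  ke_df <- data.frame(
    ke_id = vapply(kes, `[[`, "", "ke_id"),
    title = vapply(kes, `[[`, "", "title"),
    description = vapply(kes, `[[`, "", "description"),
    stringsAsFactors = FALSE)
  write_table_strict(ke_df, kes_path)

  aop_rows <- do.call(rbind, lapply(aops, function(a) {
    data.frame(aop_id = a$aop_id, title = a$title, ke_id = a$ke_ids,
               position = seq_along(a$ke_ids),
               role = unname(a$roles[a$ke_ids]),
               stringsAsFactors = FALSE)
  }))
  write_table_strict(aop_rows, aops_path)

  ker_rows <- do.call(rbind, lapply(aops, function(a) {
    if (nrow(a$ker_edges) == 0) return(NULL)
    data.frame(aop_id = a$aop_id,
               upstream_ke = a$ker_edges[, 1],
               downstream_ke = a$ker_edges[, 2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ker_rows)) {
    ker_rows <- data.frame(aop_id = character(0), upstream_ke = character(0),
                           downstream_ke = character(0))
  }
  write_table_strict(ker_rows, ker_path)
  invisible(NULL)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes within a
#' line are deduplicated; a line with fewer than two fields is a format
#' error reported with its line number.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols; the
#'   `description` attribute on each element carries the second GMT field.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop("format error in ", basename(path), " line ", i,
           ": expected at least 2 tab-separated fields", call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- fields[2]
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(genes)), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects columns `comparison_id`, `gene`, `log2fc`, `adj_p`; one row per
#' gene per comparison.
#'
#' @param path file path.
#' @return data.frame with numeric `log2fc` and `adj_p`.
#' @export
read_deg_table <- function(path) {
  df <- read_table_strict(path, c("comparison_id", "gene", "log2fc", "adj_p"))
  df$log2fc <- as.numeric(df$log2fc)
  df$adj_p <- as.numeric(df$adj_p)
  dup <- duplicated(df[, c("comparison_id", "gene")])
  if (any(dup)) {
    stop("integrity error: duplicated (comparison_id, gene) rows in ",
         basename(path), call. = FALSE)
  }
  df
}

#' Read a chemical-gene association table
#'
#' Expects columns `chemical_id`, `name`, `cas`, `gene` with one row per
#' chemical-gene link (CTD style).
#'
#' @param path file path.
#' @return named list of chemical profiles, each with `chemical_id`,
#'   `name`, `cas` and a character vector `genes`.
#' @export
read_chemical_table <- function(path) {
  df <- read_table_strict(path, c("chemical_id", "name", "cas", "gene"))
  profs <- lapply(split(df, df$chemical_id), function(block) {
    list(chemical_id = block$chemical_id[1], name = block$name[1],
         cas = block$cas[1], genes = unique(block$gene))
  })
  profs
}

#' Read a sourced edge list
#'
#' Expects columns `gene_a`, `gene_b`, `n_sources`, `directed`
#' (`TRUE`/`FALSE`).  Undirected edges are canonicalized so that
#' `gene_a < gene_b`.
#'
#' @param path file path.
#' @return data.frame of edges with integer `n_sources` and logical
#'   `directed`.
#' @export
read_edge_table <- function(path) {
  df <- read_table_strict(path, c("gene_a", "gene_b", "n_sources", "directed"))
  df$n_sources <- as.integer(df$n_sources)
  df$directed <- toupper(df$directed) %in% c("TRUE", "T", "1")
  if (any(df$n_sources < 1L, na.rm = TRUE)) {
    stop("integrity error: n_sources must be >= 1", call. = FALSE)
  }
  flip <- !df$directed & df$gene_a > df$gene_b
  tmp <- df$gene_a[flip]
  df$gene_a[flip] <- df$gene_b[flip]
  df$gene_b[flip] <- tmp
  df
}

#' Filter differentially expressed genes
#'
#' Keeps genes whose absolute linear fold change exceeds `fc_threshold`
#' (i.e. `|log2FC| > log2(fc_threshold)`) and whose adjusted p-value is
#' strictly below `p_threshold`.  Both comparisons are strict, matching the
#' usual "|FC| > 1.5 and adjusted p < 0.05" convention.
#'
#' @param deg_table data.frame with columns `gene`, `log2fc`, `adj_p`
#'   (a `comparison_id` column is allowed and ignored).
#' @param fc_threshold positive linear fold-change cut (default 1.5).
#' @param p_threshold adjusted p-value cut (default 0.05).
#' @return character vector of gene symbols passing both filters.
#' @export
filter_degs <- function(deg_table, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  ok <- is.finite(deg_table$log2fc) & is.finite(deg_table$adj_p)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite values skipped")
  }
  df <- deg_table[ok, , drop = FALSE]
  keep <- abs(df$log2fc) > log2(fc_threshold) & df$adj_p < p_threshold
  unique(df$gene[keep])
}
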