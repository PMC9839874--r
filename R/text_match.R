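# Text-matching engine: KE descriptions are scored against gene-set term
# descriptions with an IDF-weighted Jaccard index over normalized tokens.

#' Load the shipped concept dictionary
#'
#' The dictionary is a two-column TSV (`pattern`, `replacement`).  Rows whose
#' pattern contains a space are multiword concepts collapsed into a single
#' token (e.g. "positive regulation" -> "upregulated"); single-word rows are
#' variant-to-root mappings applied during token rooting.  Replacement tokens
#' are protected from further rooting, which makes the mapping idempotent.
#'
#' @param path optional path to a user dictionary in the same format;
#'   defaults to the dictionary shipped with the package.
#' @return list with components `phrases` (named character vector,
#'   names = multiword patterns) and `roots` (named character vector,
#'   names = variant tokens, including identity entries for every
#'   replacement token).
#' @export
load_concept_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "concepts.tsv", package = "aopfinger")
  }
  df <- read_table_strict(path, c("pattern", "replacement"))
  is_phrase <- grepl(" ", df$pattern, fixed = TRUE)
  phrases <- df$replacement[is_phrase]
  names(phrases) <- df$pattern[is_phrase]
  # longest-phrase-first application order
  phrases <- phrases[order(-nchar(names(phrases)))]
  roots <- df$replacement[!is_phrase]
  names(roots) <- df$pattern[!is_phrase]
  # every replacement token maps to itself, so rooting is idempotent
  protect <- setdiff(unique(df$replacement), names(roots))
  roots <- c(roots, stats::setNames(protect, protect))
  list(phrases = phrases, roots = roots)
}

#' Load the shipped English stop-word list
#'
#' @param path optional path to a plain-text stop-word list, one word per
#'   line; defaults to the frozen list shipped with the package.
#' @return character vector of stop words.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "aopfinger")
  }
  words <- readLines(path, encoding = "UTF-8")
  words[nzchar(words)]
}

root_token <- function(token, roots) {
  hit <- roots[token]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(token)
  out <- token
  stripped_inflection <- FALSE
  if (n > 5 && endsWith(token, "ing")) {
    out <- substr(token, 1, n - 3)
    stripped_inflection <- TRUE
  } else if (n > 4 && endsWith(token, "ied")) {
    out <- paste0(substr(token, 1, n - 3), "y")
  } else if (n > 4 && endsWith(token, "ed")) {
    out <- substr(token, 1, n - 2)
    stripped_inflection <- TRUE
  } else if (n > 4 && endsWith(token, "ies")) {
    out <- paste0(substr(token, 1, n - 3), "y")
  } else if (n > 3 && endsWith(token, "es") &&
             grepl("(s|x|z|ch|sh)es$", token)) {
    out <- substr(token, 1, n - 2)
  } else if (n > 3 && endsWith(token, "s") &&
             !grepl("(ss|us|is)$", token)) {
    out <- substr(token, 1, n - 1)
  }
  # doubling repair only after -ed/-ing stripping: "stopped" -> "stopp" -> "stop"
  m <- nchar(out)
  if (stripped_inflection && m >= 3 &&
      substr(out, m, m) == substr(out, m - 1, m - 1) &&
      !grepl("[aeiou]", substr(out, m, m))) {
    out <- substr(out, 1, m - 1)
  }
  hit <- roots[out]
  if (!is.na(hit)) out <- unname(hit)
  out
}

#' Normalize free text into a token set
#'
#' Applies, in order: lower-casing, punctuation removal, multiword concept
#' collapse (longest phrase first), whitespace tokenization, stop-word
#' removal, and rule-based rooting (plural and inflection stripping with
#' doubling repair) backed by the exception dictionary.  The result is a
#' set: duplicates are removed.
#'
#' @param raw_text character scalar (may be empty).
#' @param dict concept dictionary from [load_concept_dictionary()].
#' @param stopwords character vector of stop words.
#' @return character vector of normalized tokens (possibly empty).
#' @export
preprocess <- function(raw_text,
                       dict = load_concept_dictionary(),
                       stopwords = load_stopwords()) {
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  text <- tolower(raw_text)
  text <- gsub("[\\p{P}\\p{Po}]+", " ", text, perl = TRUE)
  text <- paste0(" ", gsub("\\s+", " ", text), " ")
  for (phrase in names(dict$phrases)) {
    text <- gsub(paste0(" ", phrase, " "),
                 paste0(" ", dict$phrases[[phrase]], " "),
                 text, fixed = TRUE)
  }
  tokens <- strsplit(trimws(text), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!(tokens %in% stopwords)]
  tokens <- vapply(tokens, root_token, "", roots = dict$roots)
  unique(unname(tokens))
}

#' Build an inverse-document-frequency model
#'
#' Document frequency counts how many documents of the corpus (key events
#' and gene-set terms combined) contain each token; the weight is
#' `idf(t) = ln(n_docs / df(t))`, so a token present in every document
#' weighs zero and rarer tokens weigh more.
#'
#' @param corpus list of token sets (character vectors), one per document.
#' @return list with `n_docs`, `df` (named integer vector) and `idf`
#'   (named numeric vector).
#' @export
build_idf <- function(corpus) {
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  all_tokens <- unlist(lapply(corpus, unique), use.names = FALSE)
  df <- table(all_tokens)
  df <- stats::setNames(as.integer(df), names(df))
  n_docs <- length(corpus)
  idf <- log(n_docs / df)
  list(n_docs = n_docs, df = df, idf = idf)
}

idf_lookup <- function(tokens, idf_model) {
  w <- idf_model$idf[tokens]
  missing <- is.na(w)
  if (any(missing)) {
    # token never seen when the model was built: treat as df = 1 (maximal idf)
    w[missing] <- log(idf_model$n_docs)
  }
  stats::setNames(as.numeric(w), tokens)
}

#' IDF-weighted Jaccard similarity between two token sets
#'
#' Each shared token contributes its IDF weight rather than 1:
#' `sum(idf over intersection) / sum(idf over union)`.  Returns 0 when the
#' union is empty or carries zero total weight.
#'
#' @param a,b character vectors of tokens.
#' @param idf_model model from [build_idf()].
#' @return similarity in \[0, 1\].
#' @export
weighted_jaccard <- function(a, b, idf_model) {
  a <- unique(a); b <- unique(b)
  union_t <- union(a, b)
  if (length(union_t) == 0) return(0)
  w <- idf_lookup(union_t, idf_model)
  denom <- sum(w)
  if (denom <= 0) return(0)
  sum(w[intersect(a, b)]) / denom
}

#' Rank candidate gene-set terms for a key event
#'
#' Scores every term's token set against the KE's token set with
#' [weighted_jaccard()] and returns the top `k` matches in descending
#' score order.  Ties are broken by `term_id` (lexicographic ascending) so
#' the ranking is deterministic and invariant to input order.  Terms with a
#' score of exactly zero (no shared token) are not considered matches.
#'
#' @param ke_tokens token set of the key event description.
#' @param term_tokens named list of token sets, names are term ids.
#' @param idf_model model from [build_idf()].
#' @param ke_id id recorded on the returned matches.
#' @param k number of candidates to retain (default 5).
#' @return data.frame with columns `ke_id`, `term_id`, `score`, `rank`,
#'   `status` (all `"candidate"`).
#' @export
rank_candidates <- function(ke_tokens, term_tokens, idf_model,
                            ke_id = NA_character_, k = 5) {
  stopifnot(k >= 1)
  if (length(term_tokens) == 0) {
    return(data.frame(ke_id = character(0), term_id = character(0),
                      score = numeric(0), rank = integer(0),
                      status = character(0)))
  }
  ids <- names(term_tokens)
  scores <- vapply(term_tokens, weighted_jaccard, 0.0,
                   b = ke_tokens, idf_model = idf_model)
  ord <- order(-scores, ids)
  ord <- ord[scores[ord] > 0]
  ord <- utils::head(ord, k)
  data.frame(ke_id = rep(ke_id, length(ord)), term_id = ids[ord],
             score = unname(scores[ord]), rank = seq_along(ord),
             status = rep("candidate", length(ord)),
             stringsAsFactors = FALSE)
}

#' Annotate a set of key events against a term collection
#'
#' Convenience wrapper: preprocesses all KE and term descriptions, builds
#' the IDF model over the combined corpus, and ranks the top `k` candidate
#' terms for every KE.
#'
#' @param kes named list of key event records (`ke_id`, `description`);
#'   typically `read_aop_tables()$kes`.
#' @param terms data.frame with columns `term_id` and `description`.
#' @param k candidates per KE (default 5).
#' @param dict,stopwords see [preprocess()].
#' @return data.frame of candidate matches across all KEs.
#' @export
annotate_kes <- function(kes, terms, k = 5,
                         dict = load_concept_dictionary(),
                         stopwords = load_stopwords()) {
  ke_tok <- lapply(kes, function(ke) preprocess(ke$description, dict, stopwords))
  names(ke_tok) <- vapply(kes, `[[`, "", "ke_id")
  term_tok <- lapply(terms$description, preprocess, dict = dict,
                     stopwords = stopwords)
  names(term_tok) <- terms$term_id
  idf <- build_idf(c(ke_tok, term_tok))
  out <- lapply(names(ke_tok), function(kid) {
    rank_candidates(ke_tok[[kid]], term_tok, idf, ke_id = kid, k = k)
  })
  do.call(rbind, out)
}

#' Assemble the gene set of a key event from accepted matches
#'
#' The KE gene set is the union of genes over its accepted (or manually
#' added) term matches.  A term without human genes falls back to the human
#' orthologs of its non-human (mouse/rat) genes; if every accepted term
#' remains empty after the fallback, the KE is dropped (return `NULL`).
#'
#' @param ke_id key event id.
#' @param accepted data.frame of matches for this KE with columns
#'   `term_id` and `status`; only rows with status `accepted` or `manual`
#'   are used (at most 5).
#' @param term_genes named list term_id -> character vector of human genes.
#' @param alt_genes optional named list term_id -> character vector of
#'   non-human genes used for the ortholog fallback.
#' @param orthologs optional data.frame with columns `species_gene`,
#'   `human_gene`.
#' @return list with `ke_id` and `genes`, or `NULL` when the KE resolves
#'   to no genes.
#' @export
assemble_ke_gene_set <- function(ke_id, accepted, term_genes,
                                 alt_genes = list(), orthologs = NULL) {
  use <- accepted[accepted$status %in% c("accepted", "manual"), , drop = FALSE]
  if (nrow(use) > 5) {
    stop("integrity error: more than 5 accepted matches for ", ke_id,
         call. = FALSE)
  }
  unknown <- setdiff(use$term_id, names(term_genes))
  if (length(unknown) > 0) {
    stop("integrity error: accepted match references unknown term(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- character(0)
  for (tid in use$term_id) {
    g <- term_genes[[tid]]
    if (length(g) == 0 && !is.null(orthologs) && !is.null(alt_genes[[tid]])) {
      g <- orthologs$human_gene[orthologs$species_gene %in% alt_genes[[tid]]]
    }
    genes <- union(genes, g)
  }
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) return(NULL)
  list(ke_id = ke_id, genes = sort(unique(genes)))
}

#' Build all KE gene sets from a curated candidate table
#'
#' Applies [assemble_ke_gene_set()] per KE and reports dropped KEs.
#'
#' @param matches data.frame of matches (columns `ke_id`, `term_id`,
#'   `status`).
#' @param term_genes named list term_id -> human genes.
#' @param alt_genes,orthologs see [assemble_ke_gene_set()].
#' @return list with `ke_sets` (named list ke_id -> gene vector) and
#'   `dropped` (character vector of KE ids that resolved to no genes).
#' @export
build_ke_gene_sets <- function(matches, term_genes, alt_genes = list(),
                               orthologs = NULL) {
  ke_ids <- unique(matches$ke_id[matches$status %in% c("accepted", "manual")])
  ke_sets <- list()
  dropped <- character(0)
  for (kid in ke_ids) {
    res <- assemble_ke_gene_set(
      kid, matches[matches$ke_id == kid, , drop = FALSE],
      term_genes, alt_genes, orthologs)
    if (is.null(res)) {
      dropped <- c(dropped, kid)
    } else {
      ke_sets[[kid]] <- res$genes
    }
  }
  list(ke_sets = ke_sets, dropped = dropped)
}
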