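# Deterministic generators for every input shape the pipeline consumes,
# with planted signal and emitted ground truth so each stage's recovery is
# testable without any external download.
#
# One global seed cascades to per-generator child seeds by fixed offsets,
# so each stage can be regenerated independently of the others.

SEED_OFFSETS <- c(corpus = 101L, aops = 202L, chemicals = 303L, moa = 404L,
                  edges = 505L, doseresponse = 606L, ct = 707L)

#' Fixture generator configuration
#'
#' Defaults describe a small but non-trivial study: 6 AOPs of 5 KEs each
#' (mirroring the six-pathway pulmonary-fibrosis case), a 30% chance of a
#' KE duplicating an earlier KE's gene set, 60 candidate terms over a
#' 500-gene pool, a paraphrase corruption rate of 0.2 per token, chemicals
#' drawing 60% of their genes from their target pathway, and a
#' five-point dose grid with four replicates.
#'
#' @param seed integer master seed; all generators derive their own seed
#'   from it by fixed offsets.
#' @param n_aops,n_kes_per_aop AOP scaffold dimensions.
#' @param ke_duplication_rate probability that a KE reuses an earlier KE's
#'   gene set.
#' @param n_terms,gene_pool_size term-collection dimensions.
#' @param paraphrase_noise per-token corruption probability when deriving
#'   KE descriptions from their true term's description.
#' @param n_chemicals,chemical_signal_fraction chemical-profile generator.
#' @param n_edge_genes,edge_density sourced-edge generator dimensions.
#' @param dose_grid,n_reps,noise_sd dose-response generator settings
#'   (`noise_sd` in response units).
#' @param ct_concentrations,ct_samples_per_conc,ct_noise_sd Ct-table
#'   generator settings (cycles).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_aops = 6L, n_kes_per_aop = 5L,
                           ke_duplication_rate = 0.3,
                           n_terms = 60L, gene_pool_size = 500L,
                           paraphrase_noise = 0.2,
                           n_chemicals = 10L,
                           chemical_signal_fraction = 0.6,
                           n_edge_genes = 40L, edge_density = 0.15,
                           dose_grid = c(0, 0.3, 1, 3, 10), n_reps = 4L,
                           noise_sd = 0.05,
                           ct_concentrations = c(0, 2.5, 5, 10, 100),
                           ct_samples_per_conc = 5L, ct_noise_sd = 0.05) {
  structure(as.list(environment()), class = "fixture_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

gene_pool <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a KE/term annotation corpus with planted truth
#'
#' Builds a vocabulary, draws a token description for every gene-set term,
#' and derives each KE's description by paraphrasing its true term's
#' description: every token is independently replaced by a random
#' vocabulary word with probability `paraphrase_noise`.  The truth table
#' links each KE to the term it paraphrases.
#'
#' @param cfg a [fixture_config()].
#' @return list with `terms` (data.frame `term_id`, `source`, `name`,
#'   `description`), `term_genes` (named list), `kes` (named list of KE
#'   records), and `truth` (data.frame `ke_id`, `term_id`).
#' @export
simulate_corpus <- function(cfg = fixture_config()) {
  with_seed(cfg$seed + SEED_OFFSETS[["corpus"]], {
    vocab <- sprintf("tok%03d", seq_len(240))
    pool <- gene_pool(cfg$gene_pool_size)
    n_kes <- cfg$n_aops * cfg$n_kes_per_aop
    term_ids <- sprintf("T%03d", seq_len(cfg$n_terms))
    sources <- c("GO_BP", "GO_MF", "HPO", "KEGG", "REACTOME", "WIKIPATHWAYS")
    term_desc <- vapply(term_ids, function(t)
      paste(sample(vocab, 8), collapse = " "), "")
    term_genes <- lapply(term_ids, function(t)
      sort(sample(pool, sample(10:30, 1))))
    names(term_genes) <- term_ids
    terms <- data.frame(term_id = term_ids,
                        source = sample(sources, cfg$n_terms, replace = TRUE),
                        name = term_ids, description = unname(term_desc),
                        stringsAsFactors = FALSE)
    ke_ids <- sprintf("KE%03d", seq_len(n_kes))
    true_term <- term_ids[((seq_len(n_kes) - 1) %% cfg$n_terms) + 1]
    ke_desc <- vapply(seq_len(n_kes), function(i) {
      toks <- strsplit(term_desc[[true_term[i]]], " ", fixed = TRUE)[[1]]
      corrupt <- stats::runif(length(toks)) < cfg$paraphrase_noise
      toks[corrupt] <- sample(vocab, sum(corrupt), replace = TRUE)
      paste(sample(toks), collapse = " ")
    }, "")
    kes <- lapply(seq_len(n_kes), function(i)
      list(ke_id = ke_ids[i], title = ke_ids[i], description = ke_desc[i],
           role = "KE"))
    names(kes) <- ke_ids
    list(terms = terms, term_genes = term_genes, kes = kes,
         truth = data.frame(ke_id = ke_ids, term_id = true_term,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an AOP scaffold with planted duplicate KEs and one fully
#' contained AOP
#'
#' Builds `n_aops` linear AOP chains.  Each KE of the first
#' `n_aops - 1` chains receives a fresh random gene set or, with
#' probability `ke_duplication_rate`, a copy of an earlier KE's set.  The
#' final AOP is planted fully contained: its KEs duplicate, in order, the
#' gene sets of the first chain's KEs, so after group-merging its nodes
#' and edges are a subset of the rest of the network.
#'
#' @param cfg a [fixture_config()].
#' @return list with `aops` (list of AOP records), `kes` (named list of
#'   KE records), `ke_sets` (named list), `truth` (list with
#'   `duplicate_classes`, a named list of ke_id groups, and
#'   `contained_aop`).
#' @export
simulate_aop_structure <- function(cfg = fixture_config()) {
  with_seed(cfg$seed + SEED_OFFSETS[["aops"]], {
    pool <- gene_pool(cfg$gene_pool_size)
    n_free <- cfg$n_aops - 1L
    kes <- list()
    ke_sets <- list()
    aops <- list()
    origin <- character(0)  # ke_id -> ke_id whose set it duplicates
    ctr <- 0L
    for (ai in seq_len(n_free)) {
      aid <- sprintf("AOP%02d", ai)
      ids <- character(cfg$n_kes_per_aop)
      for (j in seq_len(cfg$n_kes_per_aop)) {
        ctr <- ctr + 1L
        kid <- sprintf("KE%03d", ctr)
        ids[j] <- kid
        dup_pool <- setdiff(names(ke_sets), ids[seq_len(j - 1)])
        if (ai > 1 && length(dup_pool) > 0 &&
            stats::runif(1) < cfg$ke_duplication_rate) {
          src <- sample(dup_pool, 1)
          ke_sets[[kid]] <- ke_sets[[src]]
          origin[kid] <- if (!is.na(origin[src])) origin[src] else src
        } else {
          ke_sets[[kid]] <- sort(sample(pool, sample(10:30, 1)))
          origin[kid] <- kid
        }
        role <- if (j == 1) "MIE" else
          if (j == cfg$n_kes_per_aop) "AO" else "KE"
        kes[[kid]] <- list(ke_id = kid, title = paste("event", kid),
                           description = paste("synthetic key event", kid),
                           role = role)
      }
      edges <- cbind(upstream_ke = ids[-length(ids)],
                     downstream_ke = ids[-1])
      roles <- vapply(kes[ids], `[[`, "", "role")
      aops[[aid]] <- list(aop_id = aid, title = paste("pathway", aid),
                          ke_ids = ids, ker_edges = edges, roles = roles)
    }
    # planted contained AOP: duplicates the first chain KE-for-KE
    aid <- sprintf("AOP%02d", cfg$n_aops)
    first_ids <- aops[[1]]$ke_ids
    ids <- character(length(first_ids))
    for (j in seq_along(first_ids)) {
      ctr <- ctr + 1L
      kid <- sprintf("KE%03d", ctr)
      ids[j] <- kid
      src <- first_ids[j]
      ke_sets[[kid]] <- ke_sets[[src]]
      origin[kid] <- if (!is.na(origin[src])) origin[src] else src
      kes[[kid]] <- list(ke_id = kid, title = paste("event", kid),
                         description = paste("synthetic key event", kid),
                         role = kes[[src]]$role)
    }
    edges <- cbind(upstream_ke = ids[-length(ids)], downstream_ke = ids[-1])
    roles <- vapply(kes[ids], `[[`, "", "role")
    aops[[aid]] <- list(aop_id = aid, title = paste("pathway", aid),
                        ke_ids = ids, ker_edges = edges, roles = roles)
    classes <- split(names(origin), unname(origin))
    list(aops = aops, kes = kes, ke_sets = ke_sets,
         truth = list(duplicate_classes = classes, contained_aop = aid))
  })
}

#' Simulate chemical-gene profiles targeting labeled AOPs
#'
#' Each chemical draws `chemical_signal_fraction` of its genes from its
#' target AOP's gene set and the rest uniformly from the pool; profile
#' sizes stay within the 50-1000 screening window.
#'
#' @param cfg a [fixture_config()].
#' @param aop_sets named list aop_id -> gene set (e.g. [aop_gene_sets()]).
#' @return list with `chemicals` (named list of profiles with `category`),
#'   `relevance` (named list aop_id -> label) and `truth` (data.frame
#'   `chemical_id`, `target_aop`).
#' @export
simulate_chemicals <- function(cfg = fixture_config(), aop_sets) {
  with_seed(cfg$seed + SEED_OFFSETS[["chemicals"]], {
    pool <- gene_pool(cfg$gene_pool_size)
    aop_ids <- names(aop_sets)
    relevance <- lapply(aop_ids, function(a) paste0("cat_", a))
    names(relevance) <- aop_ids
    chems <- list()
    truth <- list()
    for (i in seq_len(cfg$n_chemicals)) {
      cid <- sprintf("CHEM%02d", i)
      target <- aop_ids[((i - 1) %% length(aop_ids)) + 1]
      size <- sample(60:120, 1)
      n_sig <- min(round(cfg$chemical_signal_fraction * size),
                   length(aop_sets[[target]]))
      sig <- sample(aop_sets[[target]], n_sig)
      bg <- sample(setdiff(pool, sig), size - n_sig)
      chems[[cid]] <- list(chemical_id = cid, name = paste("chemical", i),
                           cas = sprintf("%05d-00-%d", i, i %% 10),
                           genes = sort(c(sig, bg)),
                           category = paste0("cat_", target))
      truth[[cid]] <- data.frame(chemical_id = cid, target_aop = target,
                                 stringsAsFactors = FALSE)
    }
    list(chemicals = chems, relevance = relevance,
         truth = do.call(rbind, truth))
  })
}

#' Simulate differential-expression tables with a planted mechanism
#'
#' Produces one DEG table per comparison whose pooled, filtered union is
#' enriched for the chosen target AOPs: genes of the target AOPs receive
#' large fold changes and small adjusted p-values in a
#' `signal_fraction` of cases, background genes stay null apart from a
#' small noise floor.
#'
#' @param cfg a [fixture_config()].
#' @param aop_sets named list aop_id -> gene set.
#' @param target_aops aop ids carrying the planted signal (default: first
#'   two).
#' @param n_comparisons number of comparisons (default 3).
#' @param signal_fraction probability a target gene is differentially
#'   expressed in a given comparison (default 0.7).
#' @return list with `deg_tables` (list of data.frames) and `truth`
#'   (character vector of target aop ids).
#' @export
simulate_moa <- function(cfg = fixture_config(), aop_sets,
                         target_aops = utils::head(names(aop_sets), 2),
                         n_comparisons = 3, signal_fraction = 0.7) {
  with_seed(cfg$seed + SEED_OFFSETS[["moa"]], {
    pool <- gene_pool(cfg$gene_pool_size)
    signal_genes <- sort(unique(unlist(aop_sets[target_aops],
                                       use.names = FALSE)))
    tables <- lapply(seq_len(n_comparisons), function(ci) {
      is_sig <- stats::runif(length(signal_genes)) < signal_fraction
      bg <- setdiff(pool, signal_genes)
      bg_sig <- stats::runif(length(bg)) < 0.02  # noise floor
      gene <- c(signal_genes, bg)
      hit <- c(is_sig, bg_sig)
      log2fc <- ifelse(hit,
                       sample(c(-1, 1), length(gene), replace = TRUE) *
                         stats::runif(length(gene), 1.2, 3),
                       stats::rnorm(length(gene), 0, 0.2))
      adj_p <- ifelse(hit, stats::runif(length(gene), 1e-6, 0.01),
                      stats::runif(length(gene), 0.2, 1))
      data.frame(comparison_id = sprintf("cmp%02d", ci), gene = gene,
                 log2fc = log2fc, adj_p = adj_p, stringsAsFactors = FALSE)
    })
    list(deg_tables = tables, truth = target_aops)
  })
}

#' Simulate a sourced edge list with a well-supported core
#'
#' Random undirected gene-gene edges with mostly low source counts plus a
#' planted clique of highly supported edges, and a smaller directed
#' TF-target edge set.
#'
#' @param cfg a [fixture_config()].
#' @return list with `edges` (undirected data.frame), `tf_edges`
#'   (directed data.frame) and `truth` (character vector: the core genes).
#' @export
simulate_edges <- function(cfg = fixture_config()) {
  with_seed(cfg$seed + SEED_OFFSETS[["edges"]], {
    genes <- sprintf("N%03d", seq_len(cfg$n_edge_genes))
    pairs <- t(utils::combn(genes, 2))
    take <- stats::runif(nrow(pairs)) < cfg$edge_density
    ed <- data.frame(gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                     n_sources = sample(1:3, sum(take), replace = TRUE),
                     directed = FALSE, stringsAsFactors = FALSE)
    core <- sample(genes, 6)
    core_pairs <- t(utils::combn(sort(core), 2))
    core_df <- data.frame(gene_a = core_pairs[, 1], gene_b = core_pairs[, 2],
                          n_sources = sample(8:10, nrow(core_pairs),
                                             replace = TRUE),
                          directed = FALSE, stringsAsFactors = FALSE)
    ed <- rbind(ed, core_df)
    ed <- ed[!duplicated(ed[, c("gene_a", "gene_b")]), , drop = FALSE]
    tf <- sample(genes, 8)
    tf_rows <- do.call(rbind, lapply(tf, function(f) {
      targets <- sample(setdiff(genes, f), sample(3:6, 1))
      data.frame(gene_a = f, gene_b = targets,
                 n_sources = sample(1:2, length(targets), replace = TRUE),
                 directed = TRUE, stringsAsFactors = FALSE)
    }))
    rownames(ed) <- NULL
    list(edges = ed, tf_edges = tf_rows, truth = sort(core))
  })
}

#' Simulate dose-response expression data with known benchmark doses
#'
#' Generates genes following named mean functions with fixed parameters
#' plus Gaussian noise, and flat null genes.  The truth table carries the
#' nominal BMD of each responsive gene computed from the generating curve
#' and the generating noise level (`BMR = 1.349 * noise_sd`).
#'
#' @param cfg a [fixture_config()].
#' @param n_signal,n_null counts of responsive and flat genes.
#' @return list with `data` (long data.frame `feature`, `dose`,
#'   `response`) and `truth` (data.frame `feature`, `model`, `bmd_true`;
#'   `bmd_true` is `NA` for null genes).
#' @export
simulate_dose_response <- function(cfg = fixture_config(), n_signal = 5,
                                   n_null = 5) {
  with_seed(cfg$seed + SEED_OFFSETS[["doseresponse"]], {
    doses <- rep(cfg$dose_grid, each = cfg$n_reps)
    dmax <- max(cfg$dose_grid)
    rows <- list()
    truth <- list()
    bmr <- 1.349 * cfg$noise_sd
    for (i in seq_len(n_signal)) {
      fid <- sprintf("SIG%02d", i)
      b <- stats::runif(1, 0.5, 2) / dmax  # response range ~[0.5, 2]
      mu <- b * doses
      y <- mu + stats::rnorm(length(doses), 0, cfg$noise_sd)
      rows[[fid]] <- data.frame(feature = fid, dose = doses, response = y,
                                stringsAsFactors = FALSE)
      truth[[fid]] <- data.frame(feature = fid, model = "linear",
                                 bmd_true = bmr / b, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_null)) {
      fid <- sprintf("NUL%02d", i)
      y <- stats::rnorm(length(doses), 0, cfg$noise_sd)
      rows[[fid]] <- data.frame(feature = fid, dose = doses, response = y,
                                stringsAsFactors = FALSE)
      truth[[fid]] <- data.frame(feature = fid, model = "flat",
                                 bmd_true = NA_real_, stringsAsFactors = FALSE)
    }
    list(data = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate a qPCR Ct table with planted dose-responsive genes
#'
#' The reference gene's Ct is constant up to noise across all samples;
#' planted genes lower their Ct linearly with concentration (hence their
#' log2 fold change rises), the remaining genes are flat.
#'
#' @param cfg a [fixture_config()].
#' @param genes gene symbols to simulate (reference gene added
#'   automatically).
#' @param responsive subset of `genes` that respond to dose.
#' @param reference_gene reference symbol (default `"ACTB"`).
#' @param slope Ct decrease per concentration unit for responsive genes
#'   (default 0.03 cycles).
#' @return list with `ct` (data.frame `sample_id`, `concentration`,
#'   `gene`, `ct`) and `truth` (character vector of responsive genes).
#' @export
simulate_ct <- function(cfg = fixture_config(),
                        genes = sprintf("GENE%02d", 1:10),
                        responsive = utils::head(genes, 3),
                        reference_gene = "ACTB", slope = 0.03) {
  with_seed(cfg$seed + SEED_OFFSETS[["ct"]], {
    concs <- cfg$ct_concentrations
    rows <- list()
    idx <- 0
    for (conc in concs) {
      for (s in seq_len(cfg$ct_samples_per_conc)) {
        idx <- idx + 1
        sid <- sprintf("S%03d", idx)
        ct_ref <- 20 + stats::rnorm(1, 0, cfg$ct_noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, concentration = conc, gene = reference_gene,
          ct = ct_ref, stringsAsFactors = FALSE)
        for (g in genes) {
          base <- 25
          mu <- if (g %in% responsive) base - slope * conc else base
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, concentration = conc, gene = g,
            ct = mu + stats::rnorm(1, 0, cfg$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = do.call(rbind, rows), truth = sort(responsive))
  })
}
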