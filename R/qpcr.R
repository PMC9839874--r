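# Comparative-Ct (ddCt) fold changes, percentile outlier filtering and
# ANOVA + Tukey HSD dose-effect testing for qPCR validation.

#' Comparative-Ct fold changes
#'
#' Per sample and gene, `dCt = Ct_gene - Ct_reference`; `ddCt` subtracts
#' the mean dCt of the control-concentration samples for that gene;
#' `FC = 2^-ddCt` and `log2FC = -ddCt`.  Samples lacking a reference-gene
#' Ct are dropped with a warning.
#'
#' @param ct data.frame with columns `sample_id`, `concentration`, `gene`,
#'   `ct` (numeric cycles); one row per sample-gene measurement.  A
#'   `time_point` column, when present, is carried through and the
#'   baseline is computed within time point.
#' @param reference_gene symbol of the reference gene (default `"ACTB"`).
#' @param control_concentration concentration of the control group
#'   (default 0).
#' @return data.frame with columns of `ct` (minus the reference-gene rows)
#'   plus `dct`, `ddct`, `fc`, `log2fc`.
#' @export
ddct <- function(ct, reference_gene = "ACTB", control_concentration = 0) {
  ct$concentration <- as.numeric(ct$concentration)
  if (is.null(ct$time_point)) ct$time_point <- ""
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) stop("no reference-gene rows", call. = FALSE)
  key <- function(df) paste(df$sample_id, df$time_point, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  tgt <- ct[ct$gene != reference_gene, , drop = FALSE]
  have_ref <- key(tgt) %in% names(ref_ct)
  if (any(!have_ref)) {
    warning(sum(!have_ref), " measurement(s) dropped: sample lacks a ",
            reference_gene, " Ct")
    tgt <- tgt[have_ref, , drop = FALSE]
  }
  tgt$dct <- tgt$ct - as.numeric(ref_ct[key(tgt)])
  ctrl <- tgt[tgt$concentration == control_concentration, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control group is empty", call. = FALSE)
  base <- tapply(ctrl$dct, paste(ctrl$gene, ctrl$time_point, sep = "\r"), mean)
  gkey <- paste(tgt$gene, tgt$time_point, sep = "\r")
  if (any(!(gkey %in% names(base)))) {
    miss <- unique(tgt$gene[!(gkey %in% names(base))])
    stop("no control samples for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tgt$ddct <- tgt$dct - as.numeric(base[gkey])
  tgt$log2fc <- -tgt$ddct
  tgt$fc <- 2^tgt$log2fc
  rownames(tgt) <- NULL
  tgt
}

#' Interquartile percentile filter
#'
#' Retains the values lying within the 25th-75th percentile band of their
#' own distribution (type-7 linear-interpolation quantiles), the
#' as-printed behavior of the validation protocol.  With
#' `method = "fence"` the conventional 1.5*IQR fence is used instead.
#' Fewer than three values are returned unfiltered with a warning.
#'
#' @param values numeric vector (one gene at one concentration).
#' @param method `"quartile"` (default) or `"fence"`.
#' @return the retained values.
#' @export
percentile_filter <- function(values, method = c("quartile", "fence")) {
  method <- match.arg(method)
  if (length(values) < 3) {
    warning("fewer than 3 values; no filtering applied")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  if (method == "fence") {
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
  } else {
    lo <- q[1]
    hi <- q[2]
  }
  values[values >= lo & values <= hi]
}

#' Filter a fold-change table gene-by-gene and concentration-wise
#'
#' Applies [percentile_filter()] within each gene x concentration
#' (x time point) cell.
#'
#' @param fc_table output of [ddct()].
#' @param method see [percentile_filter()].
#' @return the retained rows of `fc_table`.
#' @export
filter_fold_changes <- function(fc_table, method = "quartile") {
  if (is.null(fc_table$time_point)) fc_table$time_point <- ""
  cell <- paste(fc_table$gene, fc_table$concentration, fc_table$time_point,
                sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(fc_table)), cell), function(idx) {
    v <- fc_table$log2fc[idx]
    retained <- suppressWarnings(percentile_filter(v, method))
    # values, not positions, are filtered; keep first occurrences of ties
    sel <- logical(length(idx))
    for (r in retained) {
      j <- which(!sel & fc_table$log2fc[idx] == r)[1]
      sel[j] <- TRUE
    }
    idx[sel]
  }), use.names = FALSE)
  out <- fc_table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post-hoc per gene
#'
#' Tests the effect of concentration on log2 fold change with a one-way
#' fixed-effects ANOVA and studentized-range pairwise comparisons.  A gene
#' needs at least two concentration groups with two or more values each;
#' otherwise it is reported untestable (`p = NA`).
#'
#' @param fc_table (filtered) fold-change table from [ddct()] /
#'   [filter_fold_changes()].
#' @param alpha significance threshold on the ANOVA p-value
#'   (default 0.05).
#' @return list with `anova` (data.frame gene, time_point, f, p,
#'   significant) and `tukey` (data.frame of pairwise comparisons).
#' @export
anova_tukey <- function(fc_table, alpha = 0.05) {
  if (is.null(fc_table$time_point)) fc_table$time_point <- ""
  cells <- split(fc_table,
                 paste(fc_table$gene, fc_table$time_point, sep = "\r"))
  arows <- list()
  trows <- list()
  for (nm in names(cells)) {
    block <- cells[[nm]]
    gene <- block$gene[1]
    tp <- block$time_point[1]
    counts <- table(block$concentration)
    if (sum(counts >= 2) < 2 || length(counts) < 2) {
      arows[[nm]] <- data.frame(gene = gene, time_point = tp,
                                f = NA_real_, p = NA_real_,
                                significant = NA, stringsAsFactors = FALSE)
      next
    }
    block$grp <- factor(block$concentration)
    fit <- stats::aov(log2fc ~ grp, data = block)
    tab <- summary(fit)[[1]]
    p <- tab[["Pr(>F)"]][1]
    arows[[nm]] <- data.frame(gene = gene, time_point = tp,
                              f = tab[["F value"]][1], p = p,
                              significant = p < alpha,
                              stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit)$grp
    trows[[nm]] <- data.frame(gene = gene, time_point = tp,
                              comparison = rownames(tk),
                              diff = tk[, "diff"], lwr = tk[, "lwr"],
                              upr = tk[, "upr"], p_adj = tk[, "p adj"],
                              stringsAsFactors = FALSE)
  }
  anova_df <- do.call(rbind, arows)
  tukey_df <- if (length(trows)) do.call(rbind, trows) else NULL
  rownames(anova_df) <- NULL
  if (!is.null(tukey_df)) rownames(tukey_df) <- NULL
  list(anova = anova_df, tukey = tukey_df)
}

#' Dose dependence of qPCR fold changes via benchmark-dose modeling
#'
#' Fits the extended qPCR model family to each gene's (filtered) log2
#' fold changes against concentration and calls a gene relevant when the
#' optimal model's lack-of-fit p-value exceeds 0.10 and BMD, BMDL and
#' BMDU are all estimable.
#'
#' @param fc_table (filtered) fold-change table.
#' @param config a [bmd_config()].
#' @return data.frame per gene (and time point): `gene`, `time_point`,
#'   `model`, `lof_p`, `bmd`, `bmdl`, `bmdu`, `relevant`.
#' @export
qpcr_dose_dependence <- function(fc_table, config = bmd_config()) {
  if (is.null(fc_table$time_point)) fc_table$time_point <- ""
  cells <- split(fc_table,
                 paste(fc_table$gene, fc_table$time_point, sep = "\r"))
  rows <- lapply(cells, function(block) {
    res <- tryCatch({
      fits <- fit_models(block$concentration, block$log2fc, "qpcr")
      if (length(fits) == 0) stop("no converged model")
      best <- fits[[1]]
      est <- estimate_bmd(best, block$concentration, block$log2fc, config)
      data.frame(gene = block$gene[1], time_point = block$time_point[1],
                 model = best$model, lof_p = best$lof_p,
                 bmd = est$bmd, bmdl = est$bmdl, bmdu = est$bmdu,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = block$gene[1], time_point = block$time_point[1],
                 model = NA_character_, lof_p = NA_real_, bmd = NA_real_,
                 bmdl = NA_real_, bmdu = NA_real_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$relevant <- !is.na(out$lof_p) & out$lof_p > 0.10 &
    is.finite(out$bmd) & is.finite(out$bmdl) & is.finite(out$bmdu)
  # a model fitting the dose means exactly has no lack of fit to detect
  exact <- is.na(out$lof_p) & is.finite(out$bmd) & is.finite(out$bmdl) &
    is.finite(out$bmdu)
  out$relevant[exact] <- TRUE
  rownames(out) <- NULL
  out
}
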