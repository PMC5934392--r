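#' Conserved subtype-specific genes across cohorts
#'
#' A gene is conserved when its MP-vs-EP two-sample t-test is significant at
#' `p_cutoff` in every cohort and (by default) the sign of the MP - EP
#' difference is identical in every cohort. Gene universes are harmonized by
#' uppercased gene id; genes absent from any cohort are dropped.
#'
#' @param cohorts a named list; each element a list with `expression` (an
#'   [expr_matrix]) and `labels` (`subtype_labels` or named MP/EP vector).
#'   At least 2 cohorts, each with both subtypes present.
#' @param p_cutoff per-cohort raw p-value threshold (default 0.001).
#' @param require_direction demand a consistent MP - EP sign across cohorts
#'   (default TRUE).
#' @param var_equal passed to [two_sample_ttest()].
#' @return list with `genes` (character vector of conserved gene ids) and
#'   `stats` (data.frame: `gene_id`, per-cohort `t_*`, `p_*`, `dir_*`,
#'   `conserved`).
#' @export
conserved_genes <- function(cohorts, p_cutoff = 0.001,
                            require_direction = TRUE, var_equal = TRUE) {
  if (length(cohorts) < 2) stop("need >= 2 cohorts")
  if (is.null(names(cohorts))) names(cohorts) <- sprintf("C%02d", seq_along(cohorts))
  per <- lapply(names(cohorts), function(id) {
    co <- cohorts[[id]]
    lab <- if (inherits(co$labels, "subtype_labels")) co$labels$label else co$labels
    mp <- names(lab)[lab == "MP"]; ep <- names(lab)[lab == "EP"]
    if (length(mp) < 2 || length(ep) < 2) {
      stop("cohort ", id, " lacks >= 2 samples of each subtype")
    }
    tt <- two_sample_ttest(co$expression, mp, ep, var_equal = var_equal)
    tt$gene_id <- toupper(tt$gene_id)
    tt
  })
  names(per) <- names(cohorts)
  shared <- Reduce(intersect, lapply(per, `[[`, "gene_id"))
  if (length(shared) == 0) stop("empty shared gene universe across cohorts")
  shared <- sort(shared)
  stats_df <- data.frame(gene_id = shared, stringsAsFactors = FALSE)
  sig <- rep(TRUE, length(shared))
  dirs <- matrix(NA_real_, length(shared), length(per))
  for (i in seq_along(per)) {
    tt <- per[[i]][match(shared, per[[i]]$gene_id), ]
    id <- names(per)[i]
    stats_df[[paste0("t_", id)]] <- tt$t
    stats_df[[paste0("p_", id)]] <- tt$p
    stats_df[[paste0("dir_", id)]] <- sign(tt$mean_diff)
    sig <- sig & tt$p < p_cutoff
    dirs[, i] <- sign(tt$mean_diff)
  }
  keep <- sig
  if (require_direction) {
    consistent <- apply(dirs, 1, function(d) all(d == d[1]) && d[1] != 0)
    keep <- keep & consistent
  }
  stats_df$conserved <- keep
  list(genes = shared[keep], stats = stats_df,
       p_cutoff = p_cutoff, require_direction = require_direction)
}

#' Rank genes by their MP/EP expression ratio
#'
#' Orders genes by the across-cohort mean of the MP - EP log2 difference,
#' descending, so MP-high genes come first. Ties break lexicographically on
#' gene id; the ranking is invariant to cohort order.
#'
#' @param genes gene ids (uppercased symbols), each present in every cohort.
#' @param cohorts as in [conserved_genes()].
#' @return data.frame ordered by rank: `gene_id`, `mean_log2_ratio`, `rank`.
#' @export
rank_by_ratio <- function(genes, cohorts) {
  if (is.null(names(cohorts))) names(cohorts) <- sprintf("C%02d", seq_along(cohorts))
  diffs <- sapply(sort(names(cohorts)), function(id) {
    co <- cohorts[[id]]
    lab <- if (inherits(co$labels, "subtype_labels")) co$labels$label else co$labels
    mp <- names(lab)[lab == "MP"]; ep <- names(lab)[lab == "EP"]
    v <- co$expression$values
    rownames(v) <- toupper(rownames(v))
    if (!all(genes %in% rownames(v))) {
      stop("cohort ", id, " lacks some requested genes")
    }
    rowMeans(v[genes, mp, drop = FALSE]) - rowMeans(v[genes, ep, drop = FALSE])
  })
  diffs <- matrix(diffs, nrow = length(genes))
  mean_ratio <- rowMeans(diffs)
  ord <- order(-mean_ratio, genes)
  data.frame(gene_id = genes[ord], mean_log2_ratio = mean_ratio[ord],
             rank = seq_along(genes), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene Pearson correlation between methylation and expression
#'
#' Correlates promoter-methylation beta-values with log2 expression across
#' shared samples; two-sided p via the t-transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param expr an [expr_matrix], log2 scale.
#' @param meth numeric matrix of beta-values (genes x samples).
#' @param genes genes to test (default: all methylation genes present in the
#'   expression matrix).
#' @return data.frame: `gene_id`, `r`, `p`, `n`, `degenerate` (TRUE when
#'   either vector has zero variance; `r` and `p` are `NA` there).
#' @export
methylation_expression_correlation <- function(expr, meth, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  .assert_scale(expr, "log2")
  if (is.null(genes)) genes <- intersect(rownames(meth), rownames(expr$values))
  shared <- intersect(colnames(meth), colnames(expr$values))
  out <- lapply(genes, function(g) {
    if (!g %in% rownames(meth) || !g %in% rownames(expr$values)) {
      stop("gene ", g, " absent from the methylation or expression matrix")
    }
    x <- expr$values[g, shared]
    y <- meth[g, shared]
    n <- length(shared)
    if (n < 3) stop("need >= 3 shared samples per gene")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene_id = g, r = NA_real_, p = NA_real_, n = n,
                        degenerate = TRUE))
    }
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), n - 2)
    }
    data.frame(gene_id = g, r = r, p = p, n = n, degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Classify samples as hypermutated
#'
#' Hypermutated iff the somatic mutation rate is strictly greater than the
#' threshold (default 11.4 mutations/Mb); a sample exactly at the threshold
#' is non-hypermutated.
#'
#' @param rates named non-negative mutation rates, mutations/Mb.
#' @param threshold mutations/Mb cutoff (default 11.4).
#' @return named character vector, `"hypermutated"` / `"non-hypermutated"`.
#' @export
classify_hypermutated <- function(rates, threshold = 11.4) {
  if (any(rates < 0)) stop("negative mutation rate")
  stats::setNames(ifelse(rates > threshold, "hypermutated", "non-hypermutated"),
                  names(rates))
}

#' Compare mutation rates between subtypes
#'
#' Two-sided Student's t-test of per-sample mutation rates between MP and EP
#' tumors, on the raw scale by default; a log10 transform is selectable for
#' heavy-tailed rates.
#'
#' @param rates named per-sample mutation rates.
#' @param labels MP/EP labels over the same samples.
#' @param log10_transform test log10(rate) instead of the raw rate.
#' @param var_equal pooled-variance test (default TRUE).
#' @return list with `t`, `p`, `mean_mp`, `mean_ep`, `n_mp`, `n_ep`.
#' @export
compare_mutation_rates <- function(rates, labels, log10_transform = FALSE,
                                   var_equal = TRUE) {
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  common <- intersect(names(rates), names(lab))
  r <- rates[common]; l <- lab[common]
  if (!all(c("MP", "EP") %in% l)) stop("both subtypes must be present")
  x <- if (log10_transform) log10(r) else r
  tt <- stats::t.test(x[l == "MP"], x[l == "EP"], var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_mp = mean(r[l == "MP"]), mean_ep = mean(r[l == "EP"]),
       n_mp = sum(l == "MP"), n_ep = sum(l == "EP"))
}

#' Write the conserved-gene report as TSV
#' @param conserved result of [conserved_genes()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_conserved_tsv <- function(conserved, file) {
  utils::write.table(conserved$stats, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
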