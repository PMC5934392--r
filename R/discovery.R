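#' Unsupervised two-cluster subtype discovery
#'
#' Agglomerative hierarchical clustering of samples with centered Pearson
#' correlation distance (1 - r) and average linkage — the classic Cluster 3.0
#' configuration for expression heat maps — cut into `k` groups. With k = 2
#' the smaller cluster is called the S (mesenchymal, MP) cluster and the
#' larger the L (epithelial, EP) cluster; an exact size tie is broken
#' deterministically by putting the cluster that contains the
#' lexicographically smallest tumor sample id into S. Outgroup samples take
#' part in the clustering (so GIST-like samples can co-cluster with MP) but
#' receive no MP/EP label; cluster sizes are counted over tumor samples only.
#'
#' @param x an [expr_matrix] (filtered, log2; typically median-centered).
#' @param k number of clusters to cut (default 2).
#' @param distance `"pearson"` (1 - correlation, default) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param include_outgroup cluster outgroup samples alongside tumors
#'   (default TRUE).
#' @return a list of class `subtype_labels`: `label` (named character, MP/EP
#'   for every tumor sample), `cluster` (named integer over all clustered
#'   samples), `tree` (the `hclust` object).
#' @export
hierarchical_cluster <- function(x, k = 2, distance = c("pearson", "euclidean"),
                                 linkage = "average", include_outgroup = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  distance <- match.arg(distance)
  use <- samples_of_type(x, if (include_outgroup) c("tumor", "outgroup") else "tumor")
  use <- sort(use)   # input-order invariance
  if (k > length(use)) stop("`k` exceeds the number of clustered samples")
  v <- x$values[, use, drop = FALSE]
  d <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(v))
  } else {
    stats::dist(t(v))
  }
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  tumors <- intersect(use, samples_of_type(x, "tumor"))
  label <- NULL
  if (k == 2) {
    sizes <- table(factor(cl[tumors], levels = c(1, 2)))
    s_cluster <- if (sizes[1] != sizes[2]) {
      as.integer(names(which.min(sizes)))
    } else {
      cl[[min(tumors)]]   # tie: cluster holding the smallest tumor id is S
    }
    label <- stats::setNames(
      ifelse(cl[tumors] == s_cluster, "MP", "EP"), tumors)
  }
  structure(list(label = label, cluster = cl, tree = tree, k = k),
            class = "subtype_labels")
}

#' @export
print.subtype_labels <- function(x, ...) {
  cat(sprintf("subtype_labels: %d samples in %d clusters\n",
              length(x$cluster), x$k))
  if (!is.null(x$label)) print(table(x$label))
  invisible(x)
}

#' Export the clustering dendrogram in Newick format
#' @param labels a `subtype_labels` object from [hierarchical_cluster()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dendrogram_newick <- function(labels, file) {
  stopifnot(inherits(labels, "subtype_labels"))
  tree <- labels$tree
  recurse <- function(i) {
    if (i < 0) return(tree$labels[-i])
    h <- tree$height[i]
    kids <- tree$merge[i, ]
    child <- function(j) {
      hj <- if (j < 0) 0 else tree$height[j]
      sprintf("%s:%g", recurse(j), h - hj)
    }
    sprintf("(%s,%s)", child(kids[1]), child(kids[2]))
  }
  writeLines(paste0(recurse(nrow(tree$merge)), ";"), file)
  invisible(file)
}

#' Per-gene two-sample t-tests between two sample groups
#'
#' Vectorized equal-variance (pooled) two-sided t-test per gene, the
#' BRB-ArrayTools default for class comparison; Welch's form is selectable.
#' Genes with zero pooled variance get t = 0, p = 1 and are flagged.
#'
#' @param x an [expr_matrix] (log2 scale).
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param var_equal pooled-variance test if TRUE (default); Welch otherwise.
#' @return data.frame with one row per gene: `gene_id`, `t`, `p`,
#'   `mean_diff` (mean A - mean B, log2 units), `degenerate`.
#' @export
two_sample_ttest <- function(x, group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs >= 2 samples")
  }
  miss <- setdiff(c(group_a, group_b), colnames(x$values))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  a <- x$values[, group_a, drop = FALSE]
  b <- x$values[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(a))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0 | !is.finite(se)
  tstat <- ifelse(degenerate, 0, (ma - mb) / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  data.frame(gene_id = rownames(x$values), t = tstat, p = p,
             mean_diff = ma - mb, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive the MP signature by the two-list cross-comparison rule
#'
#' List X holds genes differentially expressed between the MP and EP clusters
#' (two-sample t-test, `p < p_cutoff`); list Y holds genes differentially
#' expressed between MP tumors and non-tumor surrounding tissue at the same
#' cutoff. The signature is the intersection, further restricted to genes
#' whose MP - EP log2 mean difference is at least `log2(fold)` in magnitude.
#' Gene weights are the MP-vs-EP t-statistics (positive = MP-high).
#'
#' @param x an [expr_matrix], log2 scale.
#' @param labels a `subtype_labels` object (or named MP/EP character vector).
#' @param normal_samples sample ids of the non-tumor reference tissue;
#'   defaults to the matrix's `normal` annotations.
#' @param p_cutoff raw p-value threshold for both lists (default 0.001; no
#'   multiplicity correction is applied, by design).
#' @param fold fold-change cutoff on the MP-vs-EP contrast (default 2).
#' @param fold_scale `"log2"` (default; threshold `|mean diff| >= log2(fold)`)
#'   or `"linear"` (threshold on the ratio of anti-logged group means).
#' @param var_equal passed to [two_sample_ttest()].
#' @return object of class `gene_signature`: data.frame `genes` (`gene_id`,
#'   `weight`, `log2_fold_change`, `p_value`) plus the parameters used. An
#'   empty intersection yields an empty signature with a warning.
#' @export
derive_signature <- function(x, labels, normal_samples = NULL,
                             p_cutoff = 0.001, fold = 2,
                             fold_scale = c("log2", "linear"),
                             var_equal = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  fold_scale <- match.arg(fold_scale)
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  mp <- names(lab)[lab == "MP"]
  ep <- names(lab)[lab == "EP"]
  if (is.null(normal_samples)) normal_samples <- samples_of_type(x, "normal")
  if (length(intersect(normal_samples, c(mp, ep)))) {
    stop("normal samples must be disjoint from labeled tumors")
  }
  tx <- two_sample_ttest(x, mp, ep, var_equal = var_equal)
  ty <- two_sample_ttest(x, mp, normal_samples, var_equal = var_equal)
  in_x <- tx$p < p_cutoff
  in_y <- ty$p < p_cutoff
  fc_ok <- if (fold_scale == "log2") {
    abs(tx$mean_diff) >= log2(fold)
  } else {
    a <- rowMeans(2^x$values[, mp, drop = FALSE])
    b <- rowMeans(2^x$values[, ep, drop = FALSE])
    pmax(a / b, b / a) >= fold
  }
  keep <- in_x & in_y & fc_ok
  if (!any(keep)) warning("empty signature: no gene passed both lists and the fold cutoff")
  genes <- data.frame(gene_id = tx$gene_id[keep],
                      weight = tx$t[keep],
                      log2_fold_change = tx$mean_diff[keep],
                      p_value = tx$p[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, p_cutoff = p_cutoff, fold = fold,
                 fold_scale = fold_scale,
                 n_mp = length(mp), n_ep = length(ep),
                 n_normal = length(normal_samples)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d genes (%d MP-high, %d MP-low); p < %g, fold >= %g\n",
              nrow(x$genes), sum(x$genes$weight > 0), sum(x$genes$weight < 0),
              x$p_cutoff, x$fold))
  invisible(x)
}

#' Read / write a gene signature as TSV
#' @param signature a `gene_signature`.
#' @param file path.
#' @return `file` (write) or a `gene_signature` (read).
#' @export
write_signature_tsv <- function(signature, file) {
  stopifnot(inherits(signature, "gene_signature"))
  utils::write.table(signature$genes, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(file) {
  genes <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "weight", "log2_fold_change", "p_value")
  if (!all(need %in% names(genes))) {
    stop("signature TSV must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(genes = genes[, need], p_cutoff = NA_real_, fold = NA_real_,
                 fold_scale = NA_character_, n_mp = NA_integer_,
                 n_ep = NA_integer_, n_normal = NA_integer_),
            class = "gene_signature")
}
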