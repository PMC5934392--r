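#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' across-sample mean of the order statistics. Within-sample ranks are
#' preserved; ties map to the average of the tied ranks' target values. The
#' computation is delegated to [limma::normalizeQuantiles()], the standard
#' implementation for expression arrays.
#'
#' @param x an [expr_matrix] with at least 2 samples and no missing values.
#' @return the normalized [expr_matrix], same scale flag.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x$values)) {
    stop("matrix contains missing values; impute or drop_incomplete_genes() first")
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expr_matrix(v, scale = x$scale, annotations = x$annotations)
}

#' Drop genes with any missing value
#' @param x an [expr_matrix].
#' @return the [expr_matrix] restricted to complete genes.
#' @export
drop_incomplete_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- stats::complete.cases(x$values)
  subset_expr(x, genes = keep)
}

#' Log2-transform a linear-scale matrix
#'
#' @param x an [expr_matrix] flagged `linear`.
#' @param offset non-negative constant added before the log; all
#'   `value + offset` must be positive.
#' @return the [expr_matrix] on the log2 scale.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (identical(x$scale, "log2")) {
    stop("matrix is already on the log2 scale; refusing to double-transform")
  }
  if (offset < 0) stop("`offset` must be >= 0")
  if (any(x$values + offset <= 0)) {
    stop("non-positive values after adding `offset`; cannot log2-transform")
  }
  expr_matrix(log2(x$values + offset), scale = "log2",
              annotations = x$annotations)
}

#' Undo a log2 transform
#' @param x an [expr_matrix] flagged `log2`.
#' @param offset the offset used in [log2_transform()].
#' @return the [expr_matrix] on the linear scale.
#' @export
unlog2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  .assert_scale(x, "log2")
  expr_matrix(2^x$values - offset, scale = "linear",
              annotations = x$annotations)
}

#' Filter to genes varying across tissues
#'
#' Keeps gene g iff at least `min_samples` samples deviate from the gene's
#' median by at least a factor `fold` (both boundaries inclusive). On the
#' default log2 interpretation the deviation test is
#' `|x - median| >= log2(fold)`; the linear interpretation tests
#' `max(x/med, med/x) >= fold` on anti-logged values.
#'
#' @param x an [expr_matrix], log2 scale.
#' @param fold fold-change threshold (default 2).
#' @param min_samples minimum number of deviating samples (default 15).
#' @param interpretation `"log2"` (default) or `"linear"`.
#' @return the filtered [expr_matrix]; gene order preserved. If `min_samples`
#'   exceeds the sample count an empty matrix is returned with a warning.
#' @export
filter_variable_genes <- function(x, fold = 2, min_samples = 15,
                                  interpretation = c("log2", "linear")) {
  stopifnot(inherits(x, "expr_matrix"))
  interpretation <- match.arg(interpretation)
  .assert_scale(x, "log2")
  if (fold < 1) stop("`fold` must be >= 1")
  if (min_samples > ncol(x$values)) {
    warning("`min_samples` exceeds the number of samples; no gene can pass")
  }
  med <- apply(x$values, 1, stats::median)
  dev <- if (interpretation == "log2") {
    abs(x$values - med) >= log2(fold)
  } else {
    lin <- 2^x$values
    linmed <- 2^med
    pmax(lin / linmed, linmed / lin) >= fold
  }
  keep <- rowSums(dev) >= min_samples
  subset_expr(x, genes = keep)
}

#' Median-center every gene
#'
#' Subtracts each gene's median so the heat-map display scale is "relative to
#' the median across tissues". Idempotent.
#'
#' @param x an [expr_matrix], log2 scale.
#' @return the centered [expr_matrix].
#' @export
median_center_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  .assert_scale(x, "log2")
  med <- apply(x$values, 1, stats::median)
  expr_matrix(x$values - med, scale = "log2", annotations = x$annotations)
}
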