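#' Estimate per-sample tumor fraction from two reference profiles
#'
#' Models each bulk sample as a linear mixture
#' `observed ~ p * tumor_ref + (1 - p) * normal_ref` on the linear
#' (anti-log) scale and solves the single-parameter least-squares problem in
#' closed form, `p = <y - n, t - n> / ||t - n||^2`, clipped to \[0, 1\]. The
#' two reference profiles are the mean expression of tumors and of
#' surrounding non-tumor tissue, which makes the problem identifiable without
#' any machinery beyond least squares.
#'
#' @param x an [expr_matrix] of bulk samples (log2 or linear scale; log2 is
#'   anti-logged internally).
#' @param tumor_ref,normal_ref named per-gene reference profiles on the same
#'   scale as `x`.
#' @return object of class `deconv_result`: data.frame `fractions`
#'   (`sample_id`, `tumor_fraction`, `residual_norm`).
#' @export
estimate_tumor_fraction <- function(x, tumor_ref, normal_ref) {
  stopifnot(inherits(x, "expr_matrix"))
  shared <- Reduce(intersect, list(rownames(x$values), names(tumor_ref),
                                   names(normal_ref)))
  if (length(shared) < 10) stop("need >= 10 genes shared with both references")
  to_linear <- function(v) if (identical(x$scale, "log2")) 2^v else v
  y <- to_linear(x$values[shared, , drop = FALSE])
  t_ <- to_linear(tumor_ref[shared])
  n_ <- to_linear(normal_ref[shared])
  d <- t_ - n_
  denom <- sum(d^2)
  if (denom == 0) stop("tumor and normal references are identical: p is unidentifiable")
  p_raw <- as.numeric(crossprod(d, y - n_)) / denom
  p <- pmin(pmax(p_raw, 0), 1)
  fitted <- outer(d, p) + n_
  resid <- sqrt(colSums((y - fitted)^2))
  structure(list(fractions = data.frame(sample_id = colnames(y),
                                        tumor_fraction = p,
                                        residual_norm = resid,
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
                 genes_used = shared),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  f <- x$fractions$tumor_fraction
  cat(sprintf("deconv_result: %d samples; tumor fraction %.2f-%.2f (median %.2f)\n",
              length(f), min(f), max(f), stats::median(f)))
  invisible(x)
}

#' Remove the stromal contribution from bulk expression
#'
#' Two adjustment rules are shipped. `as_published` multiplies each sample's
#' linear-scale values by its tumor fraction p — the literal published rule.
#' `model_based` algebraically inverts the mixture model, recovering the
#' tumor component as `(observed - (1 - p) * normal_ref) / p`, floored at
#' zero; samples with p below `min_fraction` are left unadjusted and flagged,
#' since the inversion is unstable there. Both operate on the linear scale
#' and return to log2.
#'
#' @param x an [expr_matrix], log2 scale.
#' @param fractions a `deconv_result`, or a data.frame with `sample_id` and
#'   `tumor_fraction` (e.g. histology-derived fractions), covering every
#'   sample of `x`.
#' @param mode `"as_published"` or `"model_based"`.
#' @param normal_ref per-gene normal reference profile (log2 scale), required
#'   for `model_based`.
#' @param min_fraction smallest p at which `model_based` inversion is applied
#'   (default 0.05).
#' @param floor linear-scale floor applied before re-logging (default 2^-10,
#'   keeps log2 finite).
#' @return the adjusted [expr_matrix] (log2); attribute `skipped_samples`
#'   lists samples excluded by `min_fraction`.
#' @export
adjust_expression <- function(x, fractions, mode = c("as_published", "model_based"),
                              normal_ref = NULL, min_fraction = 0.05,
                              floor = 2^-10) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  .assert_scale(x, "log2")
  fr <- if (inherits(fractions, "deconv_result")) fractions$fractions else fractions
  if (!all(c("sample_id", "tumor_fraction") %in% names(fr))) {
    stop("`fractions` needs columns sample_id and tumor_fraction")
  }
  miss <- setdiff(colnames(x$values), fr$sample_id)
  if (length(miss)) stop("no tumor fraction for sample(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  p <- stats::setNames(fr$tumor_fraction, fr$sample_id)[colnames(x$values)]
  lin <- 2^x$values
  skipped <- character(0)
  if (mode == "as_published") {
    adj <- sweep(lin, 2, p, `*`)
  } else {
    if (is.null(normal_ref)) stop("model_based adjustment requires `normal_ref`")
    shared <- intersect(rownames(lin), names(normal_ref))
    if (length(shared) < nrow(lin)) {
      stop("`normal_ref` must cover every gene of the matrix")
    }
    n_lin <- 2^normal_ref[rownames(lin)]
    adj <- lin
    for (j in seq_len(ncol(lin))) {
      if (p[j] < min_fraction) {
        skipped <- c(skipped, colnames(lin)[j])
        next
      }
      adj[, j] <- pmax((lin[, j] - (1 - p[j]) * n_lin) / p[j], 0)
    }
  }
  out <- expr_matrix(log2(pmax(adj, floor)), scale = "log2",
                     annotations = x$annotations)
  attr(out, "skipped_samples") <- skipped
  if (length(skipped)) {
    warning(length(skipped), " sample(s) below min_fraction left unadjusted")
  }
  out
}

#' Read / write tumor fractions as two-column TSV
#' @param fractions a `deconv_result` or data.frame.
#' @param file path.
#' @return `file` (write) or a data.frame (read).
#' @export
write_fractions_tsv <- function(fractions, file) {
  fr <- if (inherits(fractions, "deconv_result")) fractions$fractions else fractions
  utils::write.table(fr[, c("sample_id", "tumor_fraction")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fractions_tsv
#' @export
read_fractions_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
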