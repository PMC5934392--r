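#' Expression matrix container
#'
#' Lightweight container for a genes x samples expression matrix together with
#' per-sample annotations and an explicit scale flag. Every downstream
#' operation checks the scale flag, so a linear-scale matrix can never be fed
#' into a step that assumes log2 values (or vice versa).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param scale either `"log2"` or `"linear"`.
#' @param annotations optional data.frame with one row per sample; must contain
#'   a `sample_id` column matching `colnames(values)`. A `tissue_type` column
#'   (values in `tumor`, `normal`, `outgroup`) and a `cohort` column are added
#'   with defaults (`tumor`, `"cohort1"`) when absent.
#'
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `annotations`.
#' @export
expr_matrix <- function(values, scale = c("log2", "linear"), annotations = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    stop("`values` must have unique rownames (gene ids)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample ids)")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(sample_id = colnames(values),
                              stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(annotations)) {
    stop("`annotations` must contain a `sample_id` column")
  }
  if (!setequal(annotations$sample_id, colnames(values)) ||
      nrow(annotations) != ncol(values)) {
    stop("`annotations$sample_id` must match the matrix sample ids exactly")
  }
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  if (!"tissue_type" %in% names(annotations)) annotations$tissue_type <- "tumor"
  if (!"cohort" %in% names(annotations)) annotations$cohort <- "cohort1"
  bad <- setdiff(unique(annotations$tissue_type), c("tumor", "normal", "outgroup"))
  if (length(bad)) {
    stop("unknown tissue_type value(s): ", paste(bad, collapse = ", "))
  }
  structure(list(values = values, scale = scale, annotations = annotations),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tt <- table(x$annotations$tissue_type)
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  tissue types:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat("  cohorts:", paste(unique(x$annotations$cohort), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [expr_matrix].
#' @param genes character vector of gene ids (or logical/integer index on rows).
#' @param samples character vector of sample ids (or logical/integer index on
#'   columns).
#' @return the subsetted [expr_matrix]; annotations follow the samples.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  ann <- x$annotations[match(colnames(v), x$annotations$sample_id), , drop = FALSE]
  expr_matrix(v, scale = x$scale, annotations = ann)
}

#' Sample ids of a given tissue type
#' @param x an [expr_matrix].
#' @param type one or more of `"tumor"`, `"normal"`, `"outgroup"`.
#' @return character vector of sample ids.
#' @export
samples_of_type <- function(x, type = "tumor") {
  stopifnot(inherits(x, "expr_matrix"))
  x$annotations$sample_id[x$annotations$tissue_type %in% type]
}

.assert_scale <- function(x, scale) {
  if (!identical(x$scale, scale)) {
    stop(sprintf("expected a %s-scale matrix but the scale flag is '%s'",
                 scale, x$scale), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write the tab-delimited expression format
#'
#' The on-disk format is a TSV with gene ids in the first column (header
#' `gene_id`) and one column per sample. Sample annotations travel in a
#' separate annotation TSV (columns `sample_id`, `tissue_type`, `cohort`).
#'
#' @param x an [expr_matrix].
#' @param file path of the expression TSV.
#' @param annotation_file optional path of the sample-annotation TSV.
#' @param scale scale flag to attach when reading (the format itself does not
#'   record it).
#' @return `read_expression_tsv` returns an [expr_matrix];
#'   `write_expression_tsv` returns `file`, invisibly.
#' @export
write_expression_tsv <- function(x, file, annotation_file = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_file)) {
    utils::write.table(x$annotations, annotation_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file, annotation_file = NULL,
                                scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") {
    stop("expected the first column of ", file, " to be `gene_id`")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  ann <- if (!is.null(annotation_file)) {
    utils::read.delim(annotation_file, stringsAsFactors = FALSE)
  } else NULL
  expr_matrix(m, scale = scale, annotations = ann)
}
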