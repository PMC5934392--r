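#' Run the full subtyping workflow end-to-end on synthetic cohorts
#'
#' Executes the complete analysis in the order the study design prescribes:
#' generate (or accept) multi-cohort data; preprocess the training cohort
#' (quantile normalization, variation filter, median centering); discover the
#' two subtypes by unsupervised clustering; derive the signature by the
#' two-list rule; train the BCCP and estimate its robustness by LOOCV;
#' predict subtype in every validation cohort and test the survival split by
#' log-rank; run the pooled subtype-by-chemotherapy interaction analysis on
#' the stage II-IV no-metastasis subset; select conserved genes across all
#' cohorts. Every stage's parameters and row/gene counts are recorded in the
#' returned summary, which is deterministic given (`config$seed`, settings).
#'
#' @param config a [simulation_config()]; its cohorts are generated
#'   internally, the first being the training cohort.
#' @param cohorts optional pre-generated list from [generate_cohort_set()]
#'   (overrides generation; `config` still supplies thresholds' context).
#' @param p_cutoff,fold,min_samples preprocessing/signature thresholds.
#' @param priors,in_fold_selection classifier settings.
#' @param cluster_truth use ground-truth subtype labels for the validation
#'   cohorts' conserved-gene step instead of re-clustering (default FALSE:
#'   each cohort is clustered unsupervised).
#' @return a list of class `mp_pipeline_result` with elements `signature`,
#'   `model`, `cv`, `validation` (per-cohort: labels, log-rank on OS and RFS),
#'   `interaction`, `conserved`, `counts`, `settings`.
#' @export
run_pipeline <- function(config, cohorts = NULL, p_cutoff = 0.001, fold = 2,
                         min_samples = 15, priors = "equal",
                         in_fold_selection = TRUE, cluster_truth = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cohorts)) cohorts <- generate_cohort_set(config)
  if (length(cohorts) < 1) stop("at least one (training) cohort is required")
  train <- cohorts[[1]]

  # --- preprocess training cohort
  qx <- quantile_normalize(drop_incomplete_genes(train$expression))
  fx <- filter_variable_genes(qx, fold = fold, min_samples = min_samples)
  cx <- median_center_genes(fx)

  # --- discovery on the training cohort
  clus <- hierarchical_cluster(cx, k = 2)
  sig <- derive_signature(qx, clus, p_cutoff = p_cutoff, fold = fold)
  if (nrow(sig$genes) == 0) stop("discovery produced an empty signature")

  # --- classifier
  model <- train_bccp(qx, clus, sig, priors = priors)
  cv <- loocv_bccp(qx, clus, signature = sig,
                   in_fold_selection = in_fold_selection,
                   p_cutoff = p_cutoff, fold = fold, priors = priors)

  # --- validation cohorts: predict, then survival split
  validation <- list()
  if (length(cohorts) > 1) {
    for (id in names(cohorts)[-1]) {
      co <- cohorts[[id]]
      vq <- quantile_normalize(drop_incomplete_genes(co$expression))
      tum <- samples_of_type(vq, "tumor")
      pred <- predict_bccp(model, subset_expr(vq, samples = tum),
                           standardize = "cohort")
      cl <- co$clinical
      lab <- pred$label[cl$sample_id]
      lr_os <- if (length(unique(lab)) > 1) {
        logrank_test(cl$os_time, cl$os_event, lab)
      } else NULL
      lr_rfs <- if (length(unique(lab)) > 1) {
        logrank_test(cl$rfs_time, cl$rfs_event, lab)
      } else NULL
      validation[[id]] <- list(labels = pred, logrank_os = lr_os,
                               logrank_rfs = lr_rfs,
                               accuracy = mean(lab == co$truth$subtype[cl$sample_id]))
    }
  }

  # --- pooled interaction analysis on the adjuvant subset
  pooled_clin <- do.call(rbind, lapply(names(cohorts), function(id) cohorts[[id]]$clinical))
  pooled_lab <- do.call(c, c(list(clus$label),
                             unname(lapply(validation,
                                           function(v) v$labels$label))))
  adj <- subset_for_adjuvant_analysis(pooled_clin)
  interaction <- tryCatch(interaction_test(adj, pooled_lab),
                          error = function(e) list(error = conditionMessage(e)))

  # --- conserved genes across all cohorts
  cohort_pairs <- lapply(names(cohorts), function(id) {
    co <- cohorts[[id]]
    lab <- if (id == names(cohorts)[1]) clus$label
      else if (cluster_truth) co$truth$subtype
      else validation[[id]]$labels$label
    list(expression = co$expression, labels = lab)
  })
  names(cohort_pairs) <- names(cohorts)
  conserved <- tryCatch(conserved_genes(cohort_pairs, p_cutoff = p_cutoff),
                        error = function(e) list(error = conditionMessage(e)))

  structure(list(
    signature = sig, model = model, cv = cv, validation = validation,
    interaction = interaction, conserved = conserved,
    discovery_labels = clus,
    counts = list(n_genes_input = nrow(train$expression$values),
                  n_genes_filtered = nrow(fx$values),
                  n_signature = nrow(sig$genes),
                  n_conserved = if (is.null(conserved$genes)) NA_integer_
                                else length(conserved$genes),
                  n_training_tumors = length(clus$label)),
    settings = list(p_cutoff = p_cutoff, fold = fold,
                    min_samples = min_samples, priors = priors,
                    in_fold_selection = in_fold_selection,
                    seed = config$seed)),
    class = "mp_pipeline_result")
}

#' @export
print.mp_pipeline_result <- function(x, ...) {
  cat("mp_pipeline_result\n")
  cat(sprintf("  genes: %d input -> %d after variation filter; signature %d; conserved %s\n",
              x$counts$n_genes_input, x$counts$n_genes_filtered,
              x$counts$n_signature, x$counts$n_conserved))
  cat(sprintf("  LOOCV: misclassification %.3f (sens %.3f, spec %.3f)\n",
              x$cv$misclassification_rate, x$cv$sensitivity_mp,
              x$cv$specificity_mp))
  for (id in names(x$validation)) {
    v <- x$validation[[id]]
    cat(sprintf("  %s: accuracy %.3f, log-rank RFS p = %.3g\n", id,
                v$accuracy, if (is.null(v$logrank_rfs)) NA else v$logrank_rfs$p))
  }
  if (is.null(x$interaction$error)) {
    cat(sprintf("  interaction p = %.3g; chemo HR (EP) %.2f, (MP) %.2f\n",
                x$interaction$interaction_p,
                x$interaction$stratified$hr[x$interaction$stratified$subtype == "EP"],
                x$interaction$stratified$hr[x$interaction$stratified$subtype == "MP"]))
  }
  invisible(x)
}

#' Machine-readable JSON summary of a pipeline run
#' @param result an `mp_pipeline_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pipeline_json <- function(result, file) {
  stopifnot(inherits(result, "mp_pipeline_result"))
  summary <- list(
    settings = result$settings,
    counts = result$counts,
    loocv = list(misclassification = result$cv$misclassification_rate,
                 sensitivity_mp = result$cv$sensitivity_mp,
                 specificity_mp = result$cv$specificity_mp),
    validation = lapply(result$validation, function(v) list(
      accuracy = v$accuracy,
      logrank_os_p = if (is.null(v$logrank_os)) NULL else v$logrank_os$p,
      logrank_rfs_p = if (is.null(v$logrank_rfs)) NULL else v$logrank_rfs$p)),
    interaction = if (is.null(result$interaction$error)) list(
      p = result$interaction$interaction_p,
      hr_chemo_ep = result$interaction$stratified$hr[
        result$interaction$stratified$subtype == "EP"],
      hr_chemo_mp = result$interaction$stratified$hr[
        result$interaction$stratified$subtype == "MP"]) else NULL,
    signature_genes = result$signature$genes$gene_id,
    conserved_genes = result$conserved$genes)
  jsonlite::write_json(summary, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
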