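#' Train a Bayesian compound covariate predictor (BCCP)
#'
#' The compound covariate of a sample is the t-statistic-weighted sum of its
#' standardized signature-gene expression, `c = sum_g t_g * z_g`. Training
#' records the per-gene standardization (mean, sd of the training tumors), the
#' per-class means of c, the pooled within-class sd of c (classical
#' compound-covariate formulation; an unequal-variance mode is selectable) and
#' the class priors. Prediction turns c into a Gaussian posterior
#' `P(MP | c) = prior_MP N(c; mu_MP, s) / sum_k prior_k N(c; mu_k, s)`.
#'
#' @param x training [expr_matrix] (log2 scale).
#' @param labels `subtype_labels` or named MP/EP character vector covering the
#'   training tumors.
#' @param signature a `gene_signature` from [derive_signature()].
#' @param priors `"equal"` (default, 0.5/0.5) or `"empirical"` (training class
#'   frequencies), or a numeric vector `c(MP = , EP = )` summing to 1.
#' @param pooled_variance use a common within-class sd of c (default TRUE).
#' @return an object of class `bccp_model`.
#' @export
train_bccp <- function(x, labels, signature, priors = "equal",
                       pooled_variance = TRUE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(signature, "gene_signature"))
  .assert_scale(x, "log2")
  if (nrow(signature$genes) == 0) stop("cannot train on an empty signature")
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  lab <- lab[!is.na(lab)]
  if (any(table(lab) < 2) || length(unique(lab)) < 2) {
    stop("each class needs >= 2 labeled training samples")
  }
  genes <- signature$genes$gene_id
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) stop("training matrix lacks signature gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  v <- x$values[genes, names(lab), drop = FALSE]
  mu_g <- rowMeans(v)
  sd_g <- apply(v, 1, stats::sd)
  if (any(sd_g == 0)) stop("signature gene with zero training variance: ",
                           genes[which(sd_g == 0)[1]])
  z <- (v - mu_g) / sd_g
  cc <- as.numeric(crossprod(signature$genes$weight, z))
  names(cc) <- colnames(z)
  mu_mp <- mean(cc[lab == "MP"])
  mu_ep <- mean(cc[lab == "EP"])
  n_mp <- sum(lab == "MP"); n_ep <- sum(lab == "EP")
  if (pooled_variance) {
    sp2 <- ((n_mp - 1) * stats::var(cc[lab == "MP"]) +
            (n_ep - 1) * stats::var(cc[lab == "EP"])) / (n_mp + n_ep - 2)
    sds <- c(MP = sqrt(sp2), EP = sqrt(sp2))
  } else {
    sds <- c(MP = stats::sd(cc[lab == "MP"]), EP = stats::sd(cc[lab == "EP"]))
  }
  if (any(sds <= 0) || any(!is.finite(sds))) {
    stop("zero pooled within-class sd of the compound covariate")
  }
  pr <- if (identical(priors, "equal")) {
    c(MP = 0.5, EP = 0.5)
  } else if (identical(priors, "empirical")) {
    c(MP = n_mp, EP = n_ep) / (n_mp + n_ep)
  } else {
    if (!is.numeric(priors) || !setequal(names(priors), c("MP", "EP")) ||
        abs(sum(priors) - 1) > 1e-8 || any(priors <= 0)) {
      stop("numeric `priors` must be c(MP=, EP=) with positive entries summing to 1")
    }
    priors[c("MP", "EP")]
  }
  structure(list(signature = signature,
                 standardization = data.frame(gene_id = genes, mean = mu_g,
                                              sd = sd_g, row.names = NULL,
                                              stringsAsFactors = FALSE),
                 class_means = c(MP = mu_mp, EP = mu_ep),
                 class_sds = sds,
                 priors = pr,
                 pooled_variance = pooled_variance,
                 training_scores = cc),
            class = "bccp_model")
}

#' @export
print.bccp_model <- function(x, ...) {
  cat(sprintf("bccp_model: %d genes; class means MP=%.3f EP=%.3f, sd=%.3f; priors MP=%.2f\n",
              nrow(x$signature$genes), x$class_means["MP"], x$class_means["EP"],
              x$class_sds["MP"], x$priors["MP"]))
  invisible(x)
}

# Resolve signature genes against a matrix: <=20% missing are tolerated by
# dropping them (weights of the remaining genes are used as-is for scoring and
# the caller is warned); more is an error.
.match_signature_genes <- function(model, x, max_missing = 0.2) {
  genes <- model$signature$genes$gene_id
  present <- genes %in% rownames(x$values)
  frac_missing <- mean(!present)
  if (frac_missing > max_missing) {
    stop(sprintf("%.0f%% of signature genes are missing (> %.0f%% allowed)",
                 100 * frac_missing, 100 * max_missing))
  }
  if (frac_missing > 0) {
    warning(sprintf("%d signature gene(s) missing; scoring on the %d present",
                    sum(!present), sum(present)))
  }
  which(present)
}

#' Compute compound covariate scores for samples
#'
#' @param model a `bccp_model`.
#' @param x an [expr_matrix] (log2 scale) holding the samples to score.
#' @param standardize `"training"` (default; z-scores use the model's stored
#'   per-gene mean/sd) or `"cohort"` (z-scores refit on this matrix's own
#'   per-gene mean/sd — the cross-platform harmonization used when a signature
#'   trained on one array platform is applied to another).
#' @return named numeric vector of compound covariate scores.
#' @export
compound_covariate <- function(model, x,
                               standardize = c("training", "cohort")) {
  stopifnot(inherits(model, "bccp_model"), inherits(x, "expr_matrix"))
  .assert_scale(x, "log2")
  standardize <- match.arg(standardize)
  idx <- .match_signature_genes(model, x)
  genes <- model$signature$genes$gene_id[idx]
  w <- model$signature$genes$weight[idx]
  v <- x$values[genes, , drop = FALSE]
  if (standardize == "training") {
    mu <- model$standardization$mean[idx]
    sg <- model$standardization$sd[idx]
  } else {
    if (ncol(v) < 3) stop("cohort standardization needs >= 3 samples")
    mu <- rowMeans(v)
    sg <- apply(v, 1, stats::sd)
    if (any(sg == 0)) stop("cohort standardization hit a zero-variance gene")
  }
  z <- (v - mu) / sg
  stats::setNames(as.numeric(crossprod(w, z)), colnames(v))
}

#' Predict MP/EP labels with a trained BCCP
#'
#' @inheritParams compound_covariate
#' @param posterior_cutoff posterior P(MP) at or above which a sample is
#'   called MP (default 0.5; the tie at exactly 0.5 goes to MP).
#' @return a `subtype_labels` object with `label` and `posterior_mp` (named
#'   numeric, P(MP | c)).
#' @export
predict_bccp <- function(model, x, standardize = c("training", "cohort"),
                         posterior_cutoff = 0.5) {
  cc <- compound_covariate(model, x, standardize = standardize)
  post <- posterior_mp(model, cc)
  label <- stats::setNames(ifelse(post >= posterior_cutoff, "MP", "EP"),
                           names(cc))
  structure(list(label = label, posterior_mp = post, score = cc, k = 2,
                 cluster = NULL, tree = NULL),
            class = "subtype_labels")
}

#' Gaussian posterior P(MP | compound covariate)
#' @param model a `bccp_model`.
#' @param score numeric vector of compound covariate values.
#' @return numeric vector of posteriors in \[0, 1\].
#' @export
posterior_mp <- function(model, score) {
  # log-space for numerical stability far from both class means
  l_mp <- log(model$priors["MP"]) +
    stats::dnorm(score, model$class_means["MP"], model$class_sds["MP"], log = TRUE)
  l_ep <- log(model$priors["EP"]) +
    stats::dnorm(score, model$class_means["EP"], model$class_sds["EP"], log = TRUE)
  stats::setNames(1 / (1 + exp(l_ep - l_mp)), names(score))
}

#' Leave-one-out cross-validation of the signature + BCCP pipeline
#'
#' Each tumor sample is held out in turn; the signature is re-derived and the
#' model re-trained on the remaining samples (honest CV, the default — the
#' left-out sample is never visible to selection or training, enforced by
#' passing folds a matrix view lacking it), then the held-out sample is
#' scored with the fold model. A `fixed_signature` mode skips in-fold
#' re-selection and reuses `signature`, reproducing the optimistic variant.
#'
#' @param x [expr_matrix] with the training tumors and the non-tumor
#'   reference samples used by list Y of the signature rule.
#' @param labels `subtype_labels` or named MP/EP vector over tumors.
#' @param signature signature derived on the full data; required in
#'   `fixed_signature` mode, otherwise only its parameters seed the in-fold
#'   derivation.
#' @param in_fold_selection re-derive the signature inside every fold
#'   (default TRUE).
#' @param p_cutoff,fold signature parameters for in-fold derivation.
#' @param priors passed to [train_bccp()].
#' @return object of class `cv_report`: confusion matrix, misclassification
#'   rate, sensitivity and specificity for MP as the positive class, and the
#'   per-sample left-out posterior. Folds whose signature comes back empty
#'   fall back to the fold's majority class (posterior `NA`) and are counted
#'   in `n_empty_signature`.
#' @export
loocv_bccp <- function(x, labels, signature = NULL, in_fold_selection = TRUE,
                       p_cutoff = 0.001, fold = 2, priors = "equal") {
  stopifnot(inherits(x, "expr_matrix"))
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  lab <- lab[!is.na(lab)]
  n <- length(lab)
  if (n < 4 || any(table(lab) < 2)) {
    stop("LOOCV needs n >= 4 with >= 2 samples per class")
  }
  if (!in_fold_selection && is.null(signature)) {
    stop("fixed-signature mode requires `signature`")
  }
  normals <- samples_of_type(x, "normal")
  pred <- character(n); post <- rep(NA_real_, n)
  names(pred) <- names(post) <- names(lab)
  n_empty <- 0L; skipped <- character(0)
  for (s in names(lab)) {
    rest <- setdiff(names(lab), s)
    lab_rest <- lab[rest]
    if (length(unique(lab_rest)) < 2 || any(table(lab_rest) < 2)) {
      skipped <- c(skipped, s)
      pred[s] <- NA_character_
      next
    }
    fold_view <- subset_expr(x, samples = c(rest, normals))
    sig_fold <- if (in_fold_selection) {
      suppressWarnings(derive_signature(fold_view, lab_rest,
                                        normal_samples = normals,
                                        p_cutoff = p_cutoff, fold = fold))
    } else signature
    if (nrow(sig_fold$genes) == 0) {
      n_empty <- n_empty + 1L
      maj <- names(which.max(table(lab_rest)))
      pred[s] <- maj
      next
    }
    mod <- train_bccp(fold_view, lab_rest, sig_fold, priors = priors)
    out <- predict_bccp(mod, subset_expr(x, samples = s),
                        standardize = "training")
    pred[s] <- out$label[[s]]
    post[s] <- out$posterior_mp[[s]]
  }
  ok <- !is.na(pred)
  confusion <- table(truth = factor(lab[ok], c("MP", "EP")),
                     predicted = factor(pred[ok], c("MP", "EP")))
  structure(list(
    confusion = confusion,
    misclassification_rate = mean(pred[ok] != lab[ok]),
    sensitivity_mp = confusion["MP", "MP"] / sum(confusion["MP", ]),
    specificity_mp = confusion["EP", "EP"] / sum(confusion["EP", ]),
    posterior_mp = post,
    predicted = pred,
    n = sum(ok),
    n_empty_signature = n_empty,
    skipped = skipped,
    in_fold_selection = in_fold_selection),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: n=%d, misclassification=%.3f, sens(MP)=%.3f, spec(MP)=%.3f\n",
              x$n, x$misclassification_rate, x$sensitivity_mp, x$specificity_mp))
  if (x$n_empty_signature > 0) {
    cat("  folds with empty in-fold signature (majority-class fallback):",
        x$n_empty_signature, "\n")
  }
  invisible(x)
}

#' Cohen's kappa between two binary labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' large-sample normal test against kappa = 0 (Fleiss standard error under
#' H0).
#'
#' @param labels_a,labels_b `subtype_labels` or named character vectors over
#'   the same sample set.
#' @return list with `kappa`, `z`, `p`, `p_observed`, `p_expected`, `n`. When
#'   both raters are constant with the same label, `p_e = 1` and kappa is
#'   undefined (`NA` with `reason`).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- if (inherits(labels_a, "subtype_labels")) labels_a$label else labels_a
  b <- if (inherits(labels_b, "subtype_labels")) labels_b$label else labels_b
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("no shared samples between the labelings")
  a <- a[common]; b <- b[common]
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  p_e <- sum(pa * pb)
  if (p_e >= 1 - 1e-12) {
    return(list(kappa = NA_real_, z = NA_real_, p = NA_real_,
                p_observed = p_o, p_expected = p_e, n = n,
                reason = "both raters constant with the same label"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se0 <- sqrt((p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2))
  z <- kappa / se0
  list(kappa = kappa, z = z, p = 2 * stats::pnorm(-abs(z)),
       p_observed = p_o, p_expected = p_e, n = n)
}

#' Linear support-vector machine reference classifier
#'
#' An independent maximum-margin classifier on the signature genes, used only
#' to test concordance with the BCCP (Cohen's kappa); the SVM itself is
#' delegated to [e1071::svm()] with a linear kernel and fixed cost, so results
#' are deterministic given the data.
#'
#' @param x training [expr_matrix].
#' @param labels training labels (MP/EP).
#' @param signature `gene_signature` whose genes define the feature space.
#' @param cost SVM cost parameter (default 1).
#' @return object of class `svm_reference` with a `predict` method via
#'   [predict_reference()].
#' @export
train_reference_classifier <- function(x, labels, signature, cost = 1) {
  stopifnot(inherits(x, "expr_matrix"), inherits(signature, "gene_signature"))
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  lab <- lab[!is.na(lab)]
  if (any(table(lab) < 2) || length(unique(lab)) < 2) {
    stop("each class needs >= 2 labeled training samples")
  }
  genes <- signature$genes$gene_id
  v <- x$values[genes, names(lab), drop = FALSE]
  mu <- rowMeans(v); sg <- apply(v, 1, stats::sd)
  if (any(sg == 0)) stop("zero-variance signature gene in SVM training data")
  z <- t((v - mu) / sg)
  fit <- e1071::svm(x = z, y = factor(lab, c("MP", "EP")), kernel = "linear",
                    cost = cost, scale = FALSE, probability = FALSE)
  structure(list(fit = fit, genes = genes, mean = mu, sd = sg),
            class = "svm_reference")
}

#' @param model an `svm_reference` from [train_reference_classifier()].
#' @param x an [expr_matrix] of samples to classify.
#' @param standardize `"training"` or `"cohort"`, as in [compound_covariate()].
#' @return a `subtype_labels` object (labels only).
#' @rdname train_reference_classifier
#' @export
predict_reference <- function(model, x, standardize = c("training", "cohort")) {
  stopifnot(inherits(model, "svm_reference"), inherits(x, "expr_matrix"))
  standardize <- match.arg(standardize)
  v <- x$values[model$genes, , drop = FALSE]
  if (standardize == "training") {
    z <- t((v - model$mean) / model$sd)
  } else {
    mu <- rowMeans(v); sg <- apply(v, 1, stats::sd)
    if (any(sg == 0)) stop("cohort standardization hit a zero-variance gene")
    z <- t((v - mu) / sg)
  }
  pred <- stats::predict(model$fit, z)
  structure(list(label = stats::setNames(as.character(pred), rownames(z)),
                 posterior_mp = NULL, k = 2, cluster = NULL, tree = NULL),
            class = "subtype_labels")
}

#' Serialize / restore a BCCP model as JSON
#' @param model a `bccp_model`.
#' @param file path.
#' @return `file` (write) or a `bccp_model` (read).
#' @export
write_bccp_json <- function(model, file) {
  stopifnot(inherits(model, "bccp_model"))
  payload <- list(
    signature = model$signature$genes,
    standardization = model$standardization,
    class_means = as.list(model$class_means),
    class_sds = as.list(model$class_sds),
    priors = as.list(model$priors),
    pooled_variance = model$pooled_variance)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_bccp_json
#' @export
read_bccp_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  sig <- structure(list(genes = p$signature, p_cutoff = NA_real_,
                        fold = NA_real_, fold_scale = NA_character_,
                        n_mp = NA_integer_, n_ep = NA_integer_,
                        n_normal = NA_integer_),
                   class = "gene_signature")
  structure(list(signature = sig,
                 standardization = p$standardization,
                 class_means = unlist(p$class_means),
                 class_sds = unlist(p$class_sds),
                 priors = unlist(p$priors),
                 pooled_variance = p$pooled_variance,
                 training_scores = NULL),
            class = "bccp_model")
}
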