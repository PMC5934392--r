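#' Configuration of the multi-cohort synthetic generator
#'
#' The generator emulates the statistical structure the subtyping analysis
#' assumes: a two-subtype mixture of bulk tumor expression profiles with a
#' planted signature, per-cohort batch shifts, stromal contamination modelled
#' as a linear mixture with a normal profile, GIST-like outgroup samples that
#' share (and amplify) the mesenchymal-direction shifts, non-tumor reference
#' samples, exponential proportional-hazards survival with a
#' subtype-by-chemotherapy interaction, promoter-methylation beta-values
#' inversely coupled to expression, and per-subtype log-normal somatic
#' mutation rates.
#'
#' @param n_cohorts number of cohorts to generate.
#' @param samples_per_cohort tumor samples per cohort.
#' @param n_genes total genes G.
#' @param n_signature_genes planted signature genes m (half up-, half
#'   down-regulated in the mesenchymal subtype).
#' @param mp_prevalence probability that a tumor is mesenchymal phenotype (MP).
#' @param effect_size log2-units mean shift delta between subtypes on the
#'   planted genes (each subtype is shifted by +/- delta/2).
#' @param gene_noise_sd per-gene residual noise sd, log2 units.
#' @param batch_shift_sd sd of the additive per-cohort, per-gene batch shift
#'   (log2 units); one shift per gene per cohort.
#' @param n_normals non-tumor (surrounding tissue) samples per cohort.
#' @param n_outgroup GIST-like outgroup samples per cohort.
#' @param outgroup_amplification multiplier on `effect_size` for outgroup
#'   samples, so they co-cluster with the MP group.
#' @param stromal_alpha,stromal_beta Beta-distribution parameters of the
#'   per-sample tumor fraction on \[0, 1\].
#' @param baseline_hazard baseline recurrence hazard, events per time unit
#'   (times are in years).
#' @param hr_mp recurrence hazard ratio of MP vs EP tumors.
#' @param hr_chemo_ep,hr_chemo_mp hazard ratio of adjuvant chemotherapy within
#'   each subtype.
#' @param chemo_assignment_prob probability a tumor sample received adjuvant
#'   chemotherapy.
#' @param censoring_rate rate of the independent exponential censoring process
#'   (0 disables censoring).
#' @param post_recurrence_rate rate of the exponential post-recurrence
#'   survival time added to recurrence times to produce overall survival.
#' @param n_methylation_genes number of signature genes given methylation
#'   beta-values (default: `min(10, n_signature_genes)`).
#' @param meth_expr_slope change in beta-value per log2-unit of expression;
#'   must be negative in the default inverse-regulation mode.
#' @param meth_noise_sd sd of the beta-value noise before clipping.
#' @param mut_meanlog_mp,mut_meanlog_ep,mut_sdlog log-normal parameters
#'   (meanlog per subtype, common sdlog) of mutation rates in mutations/Mb.
#' @param seed integer master seed; per-cohort substreams are derived from it.
#'
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_cohorts = 3,
                              samples_per_cohort = 90,
                              n_genes = 2000,
                              n_signature_genes = 50,
                              mp_prevalence = 0.35,
                              effect_size = 3,
                              gene_noise_sd = 1,
                              batch_shift_sd = 0.3,
                              n_normals = 20,
                              n_outgroup = 3,
                              outgroup_amplification = 1.5,
                              stromal_alpha = 6,
                              stromal_beta = 2,
                              baseline_hazard = 0.15,
                              hr_mp = 2,
                              hr_chemo_ep = 0.45,
                              hr_chemo_mp = 1,
                              chemo_assignment_prob = 0.6,
                              censoring_rate = 0.05,
                              post_recurrence_rate = 0.5,
                              n_methylation_genes = NULL,
                              meth_expr_slope = -0.08,
                              meth_noise_sd = 0.05,
                              mut_meanlog_mp = log(2),
                              mut_meanlog_ep = log(6),
                              mut_sdlog = 1,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_methylation_genes)) {
    cfg$n_methylation_genes <- min(10L, cfg$n_signature_genes)
  }
  counts <- c("n_cohorts", "samples_per_cohort", "n_genes", "n_signature_genes",
              "n_normals", "n_outgroup", "n_methylation_genes")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]])) {
      stop("`", f, "` must be a non-negative integer")
    }
  }
  if (cfg$samples_per_cohort < 1) stop("`samples_per_cohort` must be >= 1")
  if (cfg$n_signature_genes > cfg$n_genes) {
    stop("`n_signature_genes` cannot exceed `n_genes`")
  }
  for (f in c("mp_prevalence", "chemo_assignment_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("`", f, "` must be in [0, 1]")
  }
  if (cfg$gene_noise_sd <= 0) stop("`gene_noise_sd` must be > 0")
  for (f in c("hr_mp", "hr_chemo_ep", "hr_chemo_mp", "baseline_hazard",
              "post_recurrence_rate", "stromal_alpha", "stromal_beta")) {
    if (cfg[[f]] <= 0) stop("`", f, "` must be > 0")
  }
  if (cfg$mut_sdlog < 0) stop("`mut_sdlog` must be >= 0")
  if (cfg$censoring_rate < 0) stop("`censoring_rate` must be >= 0")
  if (cfg$n_methylation_genes > cfg$n_signature_genes) {
    stop("`n_methylation_genes` cannot exceed `n_signature_genes`")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# Counter-based substream: each cohort seeds its own RNG state so cohorts are
# independently reproducible regardless of generation order. Kept < 2^31.
.cohort_seed <- function(seed, cohort_index, stream = 0L) {
  (as.integer(seed) %% 100000L) * 10000L + cohort_index * 100L + stream
}

# cohort index recovered from ground-truth sample ids ("C03_T001" -> 3)
.cohort_index_of <- function(truth) {
  as.integer(sub("^C(\\d+)_.*$", "\\1", names(truth$subtype)[1]))
}

#' Generate one synthetic cohort with known ground truth
#'
#' Tumor samples are mixtures `p * tumor + (1 - p) * normal` on the linear
#' scale (physical mixtures add linearly), log2-transformed, with the subtype
#' shift of +/- delta/2 applied to the tumor component of the planted
#' signature genes. Outgroup (GIST-like) samples carry the MP-direction shifts
#' at `outgroup_amplification * delta` and are pure (p = 1). Recurrence-free
#' survival is exponential with log-hazard
#' `log(hr_mp) * 1[MP] + log(hr_chemo_subtype) * 1[chemo]`; overall survival is
#' the recurrence time plus an independent exponential post-recurrence time,
#' so RFS <= OS holds sample by sample; both endpoints are censored by a
#' shared independent exponential censoring time.
#'
#' @param config a [simulation_config()].
#' @param cohort_index 1-based cohort number; determinism is guaranteed given
#'   (`config$seed`, `cohort_index`).
#' @return a list with elements `expression` (an [expr_matrix], log2 scale,
#'   tumors + normals + outgroup), `clinical` (data.frame, tumor samples only)
#'   and `truth` (list: `subtype`, named per tumor sample; `signature_genes`
#'   data.frame with `gene_id` and `direction`; `tumor_fraction` named vector;
#'   `true_hrs`; `methylation_genes`).
#' @export
generate_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (cohort_index < 1 || cohort_index != round(cohort_index)) {
    stop("`cohort_index` must be a positive integer")
  }
  G <- config$n_genes
  m <- config$n_signature_genes
  nt <- config$samples_per_cohort
  gene_ids <- sprintf("G%04d", seq_len(G))
  cohort_id <- sprintf("C%02d", cohort_index)

  # gene-level architecture is shared across cohorts (master-seed stream 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.cohort_seed(config$seed, 0L))
  base_normal <- stats::rnorm(G, mean = 7, sd = 1)           # log2 baseline
  tumor_offset <- stats::rnorm(G, mean = 0, sd = 0.5)        # tumor vs normal
  sig_idx <- seq_len(m)
  # signature genes are subtype markers, not global tumor markers: their
  # tumor-profile baseline equals the normal profile, so the whole MP-vs-EP
  # and MP-vs-normal contrast comes from the planted subtype shift
  tumor_offset[sig_idx] <- 0
  direction <- rep(c(1, -1), length.out = m)                 # up/down in MP
  names(direction) <- gene_ids[sig_idx]

  set.seed(.cohort_seed(config$seed, cohort_index, 1L))
  batch <- if (config$batch_shift_sd > 0) {
    stats::rnorm(G, 0, config$batch_shift_sd)
  } else rep(0, G)

  subtype <- ifelse(stats::runif(nt) < config$mp_prevalence, "MP", "EP")
  p_frac <- stats::rbeta(nt, config$stromal_alpha, config$stromal_beta)

  tumor_profile_log2 <- base_normal + tumor_offset
  delta <- config$effect_size
  shift_for <- function(type) {
    s <- numeric(G)
    if (m > 0) {
      s[sig_idx] <- switch(type,
        MP = direction * delta / 2,
        EP = -direction * delta / 2,
        outgroup = direction * delta * config$outgroup_amplification)
    }
    s
  }

  sample_ids <- sprintf("%s_T%03d", cohort_id, seq_len(nt))
  vals <- matrix(NA_real_, G, nt, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(nt)) {
    t_log2 <- tumor_profile_log2 + shift_for(subtype[j])
    mix_lin <- p_frac[j] * 2^t_log2 + (1 - p_frac[j]) * 2^base_normal
    vals[, j] <- log2(mix_lin) + batch +
      stats::rnorm(G, 0, config$gene_noise_sd)
  }

  nn <- config$n_normals
  if (nn > 0) {
    nid <- sprintf("%s_N%03d", cohort_id, seq_len(nn))
    nv <- matrix(base_normal, G, nn, dimnames = list(gene_ids, nid)) + batch +
      matrix(stats::rnorm(G * nn, 0, config$gene_noise_sd), G, nn)
    vals <- cbind(vals, nv)
  }
  no <- config$n_outgroup
  if (no > 0) {
    oid <- sprintf("%s_G%03d", cohort_id, seq_len(no))
    oprof <- tumor_profile_log2 + shift_for("outgroup")
    ov <- matrix(oprof, G, no, dimnames = list(gene_ids, oid)) + batch +
      matrix(stats::rnorm(G * no, 0, config$gene_noise_sd), G, no)
    vals <- cbind(vals, ov)
  }

  ann <- data.frame(
    sample_id = colnames(vals),
    tissue_type = rep(c("tumor", "normal", "outgroup"), c(nt, nn, no)),
    cohort = cohort_id,
    stringsAsFactors = FALSE)
  expression <- expr_matrix(vals, scale = "log2", annotations = ann)

  # clinical table (tumor samples only), substream 2
  set.seed(.cohort_seed(config$seed, cohort_index, 2L))
  chemo <- as.integer(stats::runif(nt) < config$chemo_assignment_prob)
  age <- round(stats::rnorm(nt, 62, 10))
  sex <- sample(c("M", "F"), nt, replace = TRUE, prob = c(0.65, 0.35))
  stage <- sample(c("I", "II", "III", "IV"), nt, replace = TRUE,
                  prob = c(0.2, 0.3, 0.35, 0.15))
  distant_metastasis <- as.integer(stage == "IV" & stats::runif(nt) < 0.5)
  lauren <- sample(c("intestinal", "diffuse", "mixed"), nt, replace = TRUE,
                   prob = c(0.45, 0.4, 0.15))

  hr_chemo <- ifelse(subtype == "MP", config$hr_chemo_mp, config$hr_chemo_ep)
  lambda <- config$baseline_hazard *
    ifelse(subtype == "MP", config$hr_mp, 1) * ifelse(chemo == 1, hr_chemo, 1)
  t_rec <- stats::rexp(nt, rate = lambda)
  t_post <- stats::rexp(nt, rate = config$post_recurrence_rate)
  t_death <- t_rec + t_post
  t_cens <- if (config$censoring_rate > 0) {
    stats::rexp(nt, rate = config$censoring_rate)
  } else rep(Inf, nt)
  clinical <- data.frame(
    sample_id = sample_ids,
    os_time = pmin(t_death, t_cens),
    os_event = as.integer(t_death <= t_cens),
    rfs_time = pmin(t_rec, t_cens),
    rfs_event = as.integer(t_rec <= t_cens),
    stage = stage,
    distant_metastasis = distant_metastasis,
    age = age,
    sex = sex,
    chemo = chemo,
    lauren = lauren,
    cohort = cohort_id,
    stringsAsFactors = FALSE)

  truth <- list(
    subtype = stats::setNames(subtype, sample_ids),
    signature_genes = data.frame(
      gene_id = gene_ids[sig_idx],
      direction = ifelse(direction > 0, "up", "down"),
      stringsAsFactors = FALSE),
    tumor_fraction = stats::setNames(p_frac, sample_ids),
    true_hrs = c(hr_mp = config$hr_mp, hr_chemo_ep = config$hr_chemo_ep,
                 hr_chemo_mp = config$hr_chemo_mp),
    methylation_genes = gene_ids[seq_len(config$n_methylation_genes)],
    tumor_profile_log2 = stats::setNames(tumor_profile_log2, gene_ids),
    normal_profile_log2 = stats::setNames(base_normal, gene_ids))

  list(expression = expression, clinical = clinical, truth = truth)
}

#' Generate all cohorts of a configuration
#' @param config a [simulation_config()].
#' @return a named list of cohorts, each as returned by [generate_cohort()].
#' @export
generate_cohort_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_len(config$n_cohorts), function(i)
    generate_cohort(config, i))
  names(out) <- sprintf("C%02d", seq_len(config$n_cohorts))
  out
}

#' Generate promoter-methylation beta-values coupled to expression
#'
#' For each methylation gene the beta-value is a linear function of that
#' gene's log2 expression with negative slope (inverse regulation), centred so
#' the mean beta is 0.5, plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param truth ground-truth list from [generate_cohort()].
#' @param expr the matching [expr_matrix] (log2 scale).
#' @param config the [simulation_config()] used (supplies slope and noise sd).
#' @param mode `"inverse"` (default; requires a negative slope) or `"free"`.
#' @return numeric matrix of beta-values, methylation genes x tumor samples.
#' @export
generate_methylation <- function(truth, expr, config, mode = c("inverse", "free")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "sim_config"))
  .assert_scale(expr, "log2")
  genes <- truth$methylation_genes
  if (!all(genes %in% rownames(expr$values))) {
    stop("methylation genes must be a subset of the expression genes")
  }
  if (mode == "inverse" && config$meth_expr_slope >= 0) {
    stop("inverse-regulation mode requires a negative `meth_expr_slope`")
  }
  tumors <- samples_of_type(expr, "tumor")
  x <- expr$values[genes, tumors, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.cohort_seed(config$seed, .cohort_index_of(truth), 3L))
  centred <- x - rowMeans(x)
  beta <- 0.5 + config$meth_expr_slope * centred +
    matrix(stats::rnorm(length(x), 0, config$meth_noise_sd), nrow(x), ncol(x))
  pmin(pmax(beta, 0), 1)
}

#' Generate per-sample somatic mutation rates
#'
#' Rates (mutations/Mb) are log-normal with a subtype-specific meanlog; the
#' defaults put the epithelial subtype's distribution well above the
#' mesenchymal one, including a heavier hypermutated tail.
#'
#' @param truth ground-truth list from [generate_cohort()].
#' @param config the [simulation_config()].
#' @return named numeric vector of rates, one per tumor sample.
#' @export
generate_mutation_rates <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mut_sdlog < 0) stop("`mut_sdlog` must be >= 0")
  subtype <- truth$subtype
  meanlog <- ifelse(subtype == "MP", config$mut_meanlog_mp,
                    config$mut_meanlog_ep)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.cohort_seed(config$seed, .cohort_index_of(truth), 4L))
  if (config$mut_sdlog == 0) {
    rates <- exp(meanlog)   # degenerate: every sample at its subtype median
  } else {
    rates <- stats::rlnorm(length(subtype), meanlog, config$mut_sdlog)
  }
  stats::setNames(rates, names(subtype))
}

#' Write clinical table / ground truth to disk
#' @param clinical clinical data.frame from [generate_cohort()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_clinical_tsv <- function(clinical, file) {
  utils::write.table(clinical, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @param truth ground-truth list from [generate_cohort()].
#' @rdname write_clinical_tsv
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
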