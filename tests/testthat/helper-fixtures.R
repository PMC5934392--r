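# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

# Small two-group expression matrix with planted differential genes.
# Group A samples are named a1..aN, group B b1..bN, optional normals n1..nN.
make_blob_matrix <- function(n_genes = 100, n_planted = 10, n_a = 20, n_b = 20,
                             n_normal = 0, delta = 2, sd = 1, seed = 42,
                             baseline = 7) {
  set.seed(seed)
  ids <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)),
           if (n_normal > 0) sprintf("n%d", seq_len(n_normal)))
  tt <- rep(c("tumor", "normal"), c(n_a + n_b, n_normal))
  shift <- matrix(0, n_genes, length(ids))
  if (n_planted > 0) {
    dirs <- rep(c(1, -1), length.out = n_planted)
    shift[seq_len(n_planted), seq_len(n_a)] <- dirs * delta / 2
    shift[seq_len(n_planted), n_a + seq_len(n_b)] <- -dirs * delta / 2
  }
  v <- baseline + shift + matrix(rnorm(n_genes * length(ids), 0, sd),
                                 n_genes, length(ids))
  dimnames(v) <- list(sprintf("G%04d", seq_len(n_genes)), ids)
  expr_matrix(v, scale = "log2",
              annotations = data.frame(sample_id = ids, tissue_type = tt,
                                       cohort = "fix", stringsAsFactors = FALSE))
}

blob_labels <- function(x) {
  ids <- samples_of_type(x, "tumor")
  stats::setNames(ifelse(startsWith(ids, "a"), "MP", "EP"), ids)
}

# Simulation config with (near-)pure tumors: Beta(a, b) with tiny b puts the
# tumor fraction essentially at 1, so planted shifts are not attenuated by
# stromal mixing. Used by the parameter-recovery designs stated as
# "n per arm" two-group comparisons.
pure_config <- function(...) {
  args <- utils::modifyList(
    list(stromal_alpha = 200, stromal_beta = 1e-3,
         batch_shift_sd = 0, n_outgroup = 0),
    list(...))
  do.call(simulation_config, args)
}

# Minimal clinical table for survival unit tests.
make_clinical <- function(n = 60, seed = 1, hr_mp = 1, hr_chemo = 1,
                          base_rate = 0.3, censor_rate = 0.1) {
  set.seed(seed)
  mp <- rbinom(n, 1, 0.4)
  chemo <- rbinom(n, 1, 0.5)
  lambda <- base_rate * hr_mp^mp * hr_chemo^chemo
  t_ev <- rexp(n, lambda)
  t_c <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    rfs_time = pmin(t_ev, t_c), rfs_event = as.integer(t_ev <= t_c),
    os_time = pmin(t_ev, t_c) + 0.5, os_event = as.integer(t_ev <= t_c),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    distant_metastasis = 0L,
    age = round(rnorm(n, 60, 8)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    chemo = chemo,
    mp = mp,
    stringsAsFactors = FALSE)
}
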