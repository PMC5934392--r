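test_that("configuration rejects invalid parameters", {
  expect_error(simulation_config(n_signature_genes = 100, n_genes = 50),
               "cannot exceed")
  expect_error(simulation_config(mp_prevalence = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(gene_noise_sd = 0), "> 0")
  expect_error(simulation_config(hr_mp = -1), "> 0")
  expect_error(simulation_config(samples_per_cohort = 0), ">= 1")
  cfg <- simulation_config()
  expect_error(generate_cohort(cfg, 0), "positive integer")
})

test_that("identical config and seed reproduce byte-identical cohorts", {
  cfg <- simulation_config(n_cohorts = 2, samples_per_cohort = 30,
                           n_genes = 200, n_signature_genes = 20, seed = 11)
  a <- generate_cohort(cfg, 2)
  b <- generate_cohort(cfg, 2)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # cohorts are independently reproducible: generating cohort 1 in between
  # does not perturb cohort 2
  invisible(generate_cohort(cfg, 1))
  expect_identical(generate_cohort(cfg, 2)$expression$values,
                   a$expression$values)
  # different seeds differ
  cfg2 <- simulation_config(n_cohorts = 2, samples_per_cohort = 30,
                            n_genes = 200, n_signature_genes = 20, seed = 12)
  expect_false(identical(generate_cohort(cfg2, 2)$expression$values,
                         a$expression$values))
})

test_that("planted signature genes carry the configured mean shift", {
  cfg <- pure_config(n_cohorts = 1, samples_per_cohort = 200,
                     mp_prevalence = 0.5, n_genes = 2000,
                     n_signature_genes = 50, effect_size = 2,
                     gene_noise_sd = 1, seed = 5)
  co <- generate_cohort(cfg, 1)
  lab <- co$truth$subtype
  mp <- names(lab)[lab == "MP"]; ep <- names(lab)[lab == "EP"]
  v <- co$expression$values
  sig <- co$truth$signature_genes
  diff <- rowMeans(v[sig$gene_id, mp]) - rowMeans(v[sig$gene_id, ep])
  se <- cfg$gene_noise_sd * sqrt(1 / length(mp) + 1 / length(ep))
  signed_delta <- ifelse(sig$direction == "up", 2, -2)
  expect_true(all(abs(diff - signed_delta) < 3 * se))
  # directions recorded in the truth agree with the generated shifts
  expect_true(all(sign(diff) == ifelse(sig$direction == "up", 1, -1)))
})

test_that("null configuration produces no differential signal", {
  cfg <- pure_config(n_cohorts = 1, samples_per_cohort = 120,
                     mp_prevalence = 0.5, n_genes = 1000,
                     n_signature_genes = 10, effect_size = 0,
                     hr_mp = 1, hr_chemo_ep = 1, hr_chemo_mp = 1, seed = 21)
  co <- generate_cohort(cfg, 1)
  lab <- co$truth$subtype
  tt <- two_sample_ttest(co$expression, names(lab)[lab == "MP"],
                         names(lab)[lab == "EP"])
  # expected false positives at p < 0.001 is G * 0.001 = 1; allow 5x headroom
  expect_lte(sum(tt$p < 0.001), 5)
  lr <- logrank_test(co$clinical$rfs_time, co$clinical$rfs_event,
                     lab[co$clinical$sample_id])
  expect_gt(lr$p, 0.001)
})

test_that("RFS never exceeds OS and survival marginals match the model", {
  cfg <- simulation_config(n_cohorts = 2, samples_per_cohort = 80,
                           n_genes = 100, n_signature_genes = 10, seed = 9)
  for (i in 1:2) {
    cl <- generate_cohort(cfg, i)$clinical
    expect_true(all(cl$rfs_time <= cl$os_time + 1e-12))
    expect_true(all(cl$rfs_time > 0))
    expect_true(all(cl$os_event %in% 0:1 & cl$rfs_event %in% 0:1))
  }
  # with no censoring and hr_mp = 1, the KM curve of each arm tracks the
  # exponential exp(-lambda t) within a simulation band
  cfg0 <- simulation_config(n_cohorts = 1, samples_per_cohort = 500,
                            n_genes = 20, n_signature_genes = 2,
                            hr_mp = 1, hr_chemo_ep = 1, hr_chemo_mp = 1,
                            censoring_rate = 0, baseline_hazard = 0.2,
                            seed = 33)
  co <- generate_cohort(cfg0, 1)
  cl <- co$clinical
  expect_true(all(cl$rfs_event == 1))
  km <- km_estimate(cl$rfs_time, cl$rfs_event,
                    at = c(1, 3, 5))
  theo <- exp(-0.2 * c(1, 3, 5))
  band <- 1.96 * sqrt(theo * (1 - theo) / 500)
  expect_true(all(abs(km$at$surv - theo) < band + 0.02))
})

test_that("a pure tumor sample's expectation is the tumor profile", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 150,
                           n_genes = 400, n_signature_genes = 10,
                           stromal_alpha = 1e6, stromal_beta = 1e-6,
                           batch_shift_sd = 0, gene_noise_sd = 0.5,
                           mp_prevalence = 0, seed = 2)
  co <- generate_cohort(cfg, 1)
  # all EP, p ~= 1: per-gene mean across samples approaches the EP tumor
  # profile (tumor profile with the EP-side shift on signature genes)
  nonsig <- setdiff(rownames(co$expression$values),
                    co$truth$signature_genes$gene_id)
  m <- rowMeans(co$expression$values[nonsig, co$clinical$sample_id])
  prof <- co$truth$tumor_profile_log2[nonsig]
  se <- 0.5 / sqrt(150)
  expect_lt(max(abs(m - prof)), 5 * se)
})

test_that("methylation beta-values invert expression as configured", {
  cfg <- pure_config(n_cohorts = 1, samples_per_cohort = 100, n_genes = 200,
                     n_signature_genes = 20, n_methylation_genes = 10,
                     meth_expr_slope = -0.05, meth_noise_sd = 1e-9, seed = 4)
  co <- generate_cohort(cfg, 1)
  beta <- generate_methylation(co$truth, co$expression, cfg)
  expect_true(all(beta >= 0 & beta <= 1))
  tumors <- co$clinical$sample_id
  for (g in rownames(beta)) {
    r <- cor(co$expression$values[g, tumors], beta[g, tumors])
    expect_lt(r, -0.999)  # noiseless linear map: r = -1 up to clipping
  }
  # with noise, r matches the closed form slope*sd_x/sd_y within 0.1
  cfg2 <- pure_config(n_cohorts = 1, samples_per_cohort = 100, n_genes = 200,
                      n_signature_genes = 20, n_methylation_genes = 10,
                      meth_expr_slope = -0.05, meth_noise_sd = 0.05, seed = 4)
  co2 <- generate_cohort(cfg2, 1)
  beta2 <- generate_methylation(co2$truth, co2$expression, cfg2)
  res <- methylation_expression_correlation(co2$expression, beta2)
  sd_x <- apply(co2$expression$values[res$gene_id, tumors], 1, sd)
  r_theo <- -0.05 * sd_x / sqrt((0.05 * sd_x)^2 + 0.05^2)
  expect_true(all(abs(res$r - r_theo) < 0.1))
  # non-negative slope is rejected in inverse mode
  cfg_bad <- pure_config(n_methylation_genes = 5, meth_expr_slope = 0.1)
  expect_error(generate_methylation(co$truth, co$expression, cfg_bad),
               "negative")
})

test_that("mutation rates separate subtypes as configured", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 400,
                           n_genes = 20, n_signature_genes = 2,
                           mp_prevalence = 0.5,
                           mut_meanlog_mp = log(2), mut_meanlog_ep = log(6),
                           mut_sdlog = 1, seed = 8)
  co <- generate_cohort(cfg, 1)
  rates <- generate_mutation_rates(co$truth, cfg)
  expect_true(all(rates > 0))
  lab <- co$truth$subtype
  # EP's hypermutated fraction tracks the log-normal tail probability
  thr <- 11.4
  frac_ep <- mean(rates[lab == "EP"] > thr)
  frac_mp <- mean(rates[lab == "MP"] > thr)
  p_ep <- plnorm(thr, log(6), 1, lower.tail = FALSE)
  p_mp <- plnorm(thr, log(2), 1, lower.tail = FALSE)
  expect_lt(abs(frac_ep - p_ep), 3 * sqrt(p_ep * (1 - p_ep) / sum(lab == "EP")) + 0.01)
  expect_gt(frac_ep, frac_mp)
  # zero-variance degenerate config collapses to the per-subtype median
  cfg0 <- simulation_config(n_cohorts = 1, samples_per_cohort = 50,
                            n_genes = 20, n_signature_genes = 2,
                            mut_sdlog = 0, seed = 8)
  co0 <- generate_cohort(cfg0, 1)
  r0 <- generate_mutation_rates(co0$truth, cfg0)
  expect_true(all(r0[co0$truth$subtype == "MP"] == 2))
  expect_true(all(r0[co0$truth$subtype == "EP"] == 6))
})

test_that("expression and clinical tables round-trip through TSV", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 10,
                           n_genes = 30, n_signature_genes = 4, seed = 14)
  co <- generate_cohort(cfg, 1)
  ef <- tempfile(fileext = ".tsv"); af <- tempfile(fileext = ".tsv")
  cf <- tempfile(fileext = ".tsv"); tf <- tempfile(fileext = ".json")
  write_expression_tsv(co$expression, ef, annotation_file = af)
  back <- read_expression_tsv(ef, annotation_file = af)
  expect_equal(back$values, co$expression$values, tolerance = 1e-10)
  expect_identical(back$annotations$tissue_type,
                   co$expression$annotations$tissue_type)
  write_clinical_tsv(co$clinical, cf)
  clb <- read_clinical_tsv(cf)
  expect_equal(clb$rfs_time, co$clinical$rfs_time, tolerance = 1e-6)
  write_truth_json(co$truth, tf)
  expect_true(file.exists(tf))
})
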