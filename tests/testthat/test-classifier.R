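# shared training fixture: well-separated two-class cohort with normals
train_fixture <- function(delta = 3, sd = 1, seed = 17, n_a = 30, n_b = 50) {
  x <- make_blob_matrix(n_genes = 400, n_planted = 20, n_a = n_a, n_b = n_b,
                        n_normal = 20, delta = delta, sd = sd, seed = seed)
  lab <- blob_labels(x)
  sig <- derive_signature(x, lab)
  list(x = x, lab = lab, sig = sig, model = train_bccp(x, lab, sig))
}

test_that("compound covariate matches a brute-force sum loop", {
  fx <- train_fixture()
  cc <- compound_covariate(fx$model, fx$x)
  # independent loop oracle over the model's own standardization
  st <- fx$model$standardization
  w <- fx$model$signature$genes$weight
  for (s in sample(colnames(fx$x$values), 10)) {
    acc <- 0
    for (i in seq_along(w)) {
      z <- (fx$x$values[st$gene_id[i], s] - st$mean[i]) / st$sd[i]
      acc <- acc + w[i] * z
    }
    expect_equal(cc[[s]], acc, tolerance = 1e-12)
  }
})

test_that("compound covariate closed forms hold", {
  # single-gene signature with weight 2: c = 2 * z
  v <- matrix(c(0, 2, 4, 6), 1, 4,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  x <- expr_matrix(v, scale = "log2")
  sig <- structure(list(genes = data.frame(gene_id = "g1", weight = 2,
                                           log2_fold_change = 1,
                                           p_value = 0.001)),
                   class = "gene_signature")
  lab <- c(s1 = "EP", s2 = "EP", s3 = "MP", s4 = "MP")
  m <- train_bccp(x, lab, sig)
  cc <- compound_covariate(m, x)
  z <- (v[1, ] - mean(v[1, ])) / sd(v[1, ])
  expect_equal(unname(cc), unname(2 * z), tolerance = 1e-12)
  # all z = 0 (sample at the training mean) -> c = 0
  x0 <- expr_matrix(matrix(mean(v), 1, 1, dimnames = list("g1", "new")),
                    scale = "log2")
  expect_equal(unname(compound_covariate(m, x0)), 0, tolerance = 1e-12)
})

test_that("training is deterministic and separates separated classes", {
  fx <- train_fixture()
  m2 <- train_bccp(fx$x, fx$lab, fx$sig)
  expect_identical(fx$model$class_means, m2$class_means)
  expect_identical(fx$model$standardization, m2$standardization)
  expect_gt(abs(diff(fx$model$class_means)), fx$model$class_sds[["MP"]])
  pred <- predict_bccp(fx$model, fx$x)
  tumors <- names(fx$lab)
  expect_true(all(ifelse(fx$lab == "MP",
                         pred$posterior_mp[tumors] > 0.5,
                         pred$posterior_mp[tumors] < 0.5)))
})

test_that("randomly permuted labels yield no class separation", {
  x <- make_blob_matrix(n_genes = 300, n_planted = 20, n_a = 40, n_b = 40,
                        n_normal = 20, delta = 2, sd = 1, seed = 23)
  lab <- blob_labels(x)
  sig <- derive_signature(x, lab)
  set.seed(99)
  seps <- replicate(20, {
    plab <- stats::setNames(sample(lab), names(lab))
    m <- train_bccp(x, plab, sig)
    abs(diff(m$class_means)) / m$class_sds[["MP"]]
  })
  # under the null the standardized mean separation stays small
  expect_lt(median(seps), 1)
})

test_that("posterior has its Gaussian-model properties", {
  fx <- train_fixture()
  m <- fx$model
  mid <- mean(m$class_means)
  expect_equal(unname(posterior_mp(m, mid)), 0.5, tolerance = 1e-12)
  # c at mu_MP with 6-sigma class separation: posterior > 0.99
  m6 <- m
  m6$class_means <- c(MP = 3, EP = -3)
  m6$class_sds <- c(MP = 1, EP = 1)
  expect_gt(posterior_mp(m6, 3), 0.99)
  # monotone non-decreasing in c when mu_MP > mu_EP
  grid <- seq(min(m$class_means) - 5, max(m$class_means) + 5, length.out = 200)
  post <- posterior_mp(m, grid)
  if (m$class_means["MP"] > m$class_means["EP"]) {
    expect_true(all(diff(post) >= -1e-12))
  } else {
    expect_true(all(diff(post) <= 1e-12))
  }
  # P(MP) + P(EP) = 1: flipping the class roles complements the posterior
  mflip <- m
  mflip$class_means <- m$class_means[c(2, 1)]
  names(mflip$class_means) <- c("MP", "EP")
  expect_equal(unname(posterior_mp(m, grid) + posterior_mp(mflip, grid)),
               rep(1, length(grid)), tolerance = 1e-12)
})

test_that("unequal priors shift the decision boundary by the closed form", {
  fx <- train_fixture()
  for (q in c(0.2, 0.5, 0.8)) {
    m <- train_bccp(fx$x, fx$lab, fx$sig, priors = c(MP = q, EP = 1 - q))
    mu <- m$class_means; s <- m$class_sds[["MP"]]
    boundary <- uniroot(function(c) posterior_mp(m, c) - 0.5,
                        interval = range(mu) + c(-20, 20), tol = 1e-12)$root
    closed <- mean(mu) - s^2 * log(q / (1 - q)) / (mu[["MP"]] - mu[["EP"]])
    expect_equal(boundary, closed, tolerance = 1e-8)
  }
})

test_that("prediction is invariant to affine gene rescaling under refit", {
  fx <- train_fixture()
  pred1 <- predict_bccp(fx$model, fx$x, standardize = "cohort")
  # rescale every gene by its own positive affine map
  v2 <- fx$x$values * 3.7 + seq_len(nrow(fx$x$values))
  x2 <- expr_matrix(v2, scale = "log2", annotations = fx$x$annotations)
  pred2 <- predict_bccp(fx$model, x2, standardize = "cohort")
  expect_equal(pred1$posterior_mp, pred2$posterior_mp, tolerance = 1e-10)
  expect_identical(pred1$label, pred2$label)
})

test_that("missing signature genes degrade gracefully up to 20%", {
  fx <- train_fixture()
  genes <- fx$model$signature$genes$gene_id
  drop_few <- genes[seq_len(floor(length(genes) * 0.15))]
  x_few <- subset_expr(fx$x, genes = setdiff(rownames(fx$x$values), drop_few))
  expect_warning(p <- predict_bccp(fx$model, x_few), "missing")
  expect_gt(mean(p$label[names(fx$lab)] == fx$lab), 0.9)
  drop_many <- genes[seq_len(ceiling(length(genes) * 0.5))]
  x_many <- subset_expr(fx$x, genes = setdiff(rownames(fx$x$values), drop_many))
  expect_error(predict_bccp(fx$model, x_many), "missing")
})

test_that("LOOCV at strong signal misclassifies at most 5%", {
  x <- make_blob_matrix(n_genes = 2000, n_planted = 50, n_a = 35, n_b = 65,
                        n_normal = 30, delta = 3, sd = 1, seed = 61)
  cv <- loocv_bccp(x, blob_labels(x))
  expect_lte(cv$misclassification_rate, 0.05)
  expect_equal(cv$n, 100)
  expect_equal(sum(cv$confusion), 100)
  expect_gte(cv$sensitivity_mp, 0.9)
  expect_gte(cv$specificity_mp, 0.9)
})

test_that("LOOCV error is consistent with independent hold-out error", {
  x <- make_blob_matrix(n_genes = 1000, n_planted = 40, n_a = 35, n_b = 65,
                        n_normal = 30, delta = 3, sd = 1, seed = 62)
  lab <- blob_labels(x)
  cv <- loocv_bccp(x, lab)
  hold <- make_blob_matrix(n_genes = 1000, n_planted = 40, n_a = 35, n_b = 65,
                           n_normal = 30, delta = 3, sd = 1, seed = 63)
  sig <- derive_signature(x, lab)
  model <- train_bccp(x, lab, sig)
  pred <- predict_bccp(model, hold, standardize = "cohort")
  hold_lab <- blob_labels(hold)
  hold_err <- mean(pred$label[names(hold_lab)] != hold_lab)
  expect_lte(abs(cv$misclassification_rate - hold_err), 0.03)
})

test_that("LOOCV under the null approaches the majority-class error", {
  x <- make_blob_matrix(n_genes = 400, n_planted = 0, n_a = 30, n_b = 70,
                        n_normal = 20, delta = 0, sd = 1, seed = 64)
  set.seed(64)
  lab <- stats::setNames(sample(rep(c("MP", "EP"), c(30, 70))),
                         names(blob_labels(x)))
  cv <- loocv_bccp(x, lab)
  # majority-class error is 0.30; allow a simulation band around it
  expect_lt(abs(cv$misclassification_rate - 0.30), 0.12)
})

test_that("Cohen's kappa matches the direct formula and its edge cases", {
  # 2x2 agreement table (20, 5; 10, 65)
  a <- rep(c("MP", "MP", "EP", "EP"), c(20, 5, 10, 65))
  b <- rep(c("MP", "EP", "MP", "EP"), c(20, 5, 10, 65))
  names(a) <- names(b) <- sprintf("s%03d", seq_along(a))
  k <- cohens_kappa(a, b)
  p_o <- (20 + 65) / 100
  p_e <- (25 / 100) * (30 / 100) + (75 / 100) * (70 / 100)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e), tolerance = 1e-12)
  expect_lt(k$p, 0.05)
  # identical labelings with both classes present
  ki <- cohens_kappa(a, a)
  expect_equal(ki$kappa, 1)
  # independent random labeling: kappa near 0 at large n
  set.seed(5)
  r <- stats::setNames(sample(c("MP", "EP"), 2000, replace = TRUE),
                       sprintf("q%04d", 1:2000))
  r2 <- stats::setNames(sample(c("MP", "EP"), 2000, replace = TRUE), names(r))
  expect_lt(abs(cohens_kappa(r, r2)$kappa), 0.1)
  # both raters constant and identical: undefined
  cst <- stats::setNames(rep("MP", 10), sprintf("c%d", 1:10))
  ku <- cohens_kappa(cst, cst)
  expect_true(is.na(ku$kappa))
})

test_that("the SVM reference classifier concurs with the BCCP on clear signal", {
  fx <- train_fixture(delta = 3, sd = 1)
  svm1 <- train_reference_classifier(fx$x, fx$lab, fx$sig)
  svm2 <- train_reference_classifier(fx$x, fx$lab, fx$sig)
  p1 <- predict_reference(svm1, fx$x)
  p2 <- predict_reference(svm2, fx$x)
  expect_identical(p1$label, p2$label)  # deterministic
  bccp <- predict_bccp(fx$model, fx$x)
  tumors <- names(fx$lab)
  k <- cohens_kappa(bccp$label[tumors], p1$label[tumors])
  expect_gte(k$kappa, 0.8)
})

test_that("BCCP model round-trips through JSON", {
  fx <- train_fixture()
  f <- tempfile(fileext = ".json")
  write_bccp_json(fx$model, f)
  back <- read_bccp_json(f)
  expect_equal(back$class_means, fx$model$class_means, tolerance = 1e-12)
  expect_equal(back$priors, fx$model$priors, tolerance = 1e-12)
  cc1 <- compound_covariate(fx$model, fx$x)
  cc2 <- compound_covariate(back, fx$x)
  expect_equal(cc1, cc2, tolerance = 1e-10)
})
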