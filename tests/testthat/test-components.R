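test_that("PCA matches the dense SVD oracle and its defining properties", {
  x <- rand_matrix(10, 20, seed = 2)
  fit <- fit_components(x, k = 5, method = "pca", sign_align = FALSE)
  orc <- pca_oracle(x, 5)
  expect_true(all(abs_cor_diag(fit$scores, orc$scores) > 1 - 1e-8))
  expect_equal(unname(fit$ve), orc$share[1:5], tolerance = 1e-8)
  cc <- cor(fit$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # rank-1 input: C1 recovers the score direction with VE 1
  s <- rnorm(12); w <- rnorm(30)
  r1 <- outer(s, w)
  dimnames(r1) <- list(paste0("R", 1:12), paste0("G", 1:30))
  f1 <- fit_components(r1, k = 1, method = "pca")
  expect_equal(abs(cor(f1$scores[, 1], s)), 1, tolerance = 1e-10)
  expect_equal(unname(f1$ve), 1, tolerance = 1e-10)
  expect_error(fit_components(x, k = 11, method = "pca"),
               class = "cortexcomp_invalid_argument")
})

test_that("DME matches an independent reference implementation on small input", {
  set.seed(14)
  x <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("R", 1:8), paste0("G", 1:5)))
  fit <- fit_components(x, k = 3, method = "dme", sign_align = FALSE)
  ref <- dme_oracle(x, 3)
  expect_true(all(abs_cor_diag(fit$scores, ref) > 1 - 1e-8))
  expect_true(all(abs(fit$scores - ref %*% diag(sign(diag(cor(fit$scores, ref))))) < 1e-6))
})

test_that("DME kernel, separation and degenerate-input behavior", {
  # affinity entries in [0, 1], unit diagonal
  x <- rand_matrix(12, 6, seed = 4)
  a <- cortexcomp:::row_affinity(abs(x), "normalized_angle")
  expect_true(all(a >= 0 & a <= 1 + 1e-12))
  expect_equal(unname(diag(a)), rep(1, 12))
  # two well-separated row clusters: C1 separates them with opposite signs
  cl <- rbind(matrix(rep(c(5, 1, 1, 1, 1), each = 4), 4) + rnorm(20, 0, .05),
              matrix(rep(c(1, 1, 1, 1, 5), each = 4), 4) + rnorm(20, 0, .05))
  dimnames(cl) <- list(paste0("R", 1:8), paste0("G", 1:5))
  fc <- fit_components(cl, k = 2, method = "dme")
  expect_true(all(sign(fc$scores[1:4, 1]) == sign(fc$scores[1, 1])))
  expect_true(all(sign(fc$scores[5:8, 1]) == -sign(fc$scores[1, 1])))
  # identical rows: degenerate affinity
  same <- matrix(rep(c(1, 2, 3), each = 10), 10)
  dimnames(same) <- list(paste0("R", 1:10), paste0("G", 1:3))
  expect_error(fit_components(same, k = 2, method = "dme"),
               class = "cortexcomp_degenerate_input")
})

test_that("DME is invariant to row and column permutations up to sign", {
  x <- rand_matrix(20, 30, seed = 6)
  f0 <- fit_components(x, k = 3, method = "dme")
  set.seed(1)
  pr <- sample(20); pc <- sample(30)
  f1 <- fit_components(x[pr, pc], k = 3, method = "dme")
  expect_true(all(abs(abs(f1$scores[rownames(x), ]) - abs(f0$scores)) < 1e-6))
})

test_that("gene weights are Pearson correlations with hand-checked value", {
  x <- cbind(G1 = c(1, 2, 4), G2 = c(-1, 0, 1), G3 = c(2, 2, 2))
  rownames(x) <- paste0("R", 1:3)
  scores <- cbind(C1 = c(-1, 0, 1))
  expect_warning(w <- gene_weights(x, scores), "zero-variance")
  expect_equal(w["G1", 1], 9 / sqrt(84), tolerance = 1e-12)  # = 0.98198...
  expect_equal(w["G2", 1], 1)
  expect_equal(w["G3", 1], 0)
})

test_that("variance explained matches PCA eigenvalues and completes to 1", {
  x <- rand_matrix(12, 25, seed = 8)
  fit <- fit_components(x, k = 5, method = "pca")
  orc <- pca_oracle(x, 5)
  expect_equal(unname(variance_explained(x, fit$scores)$share),
               orc$share[1:5], tolerance = 1e-8)
  # complete orthogonal basis: shares sum to 1
  full <- fit_components(x, k = 11, method = "pca")
  expect_equal(sum(variance_explained(x, full$scores)$share), 1,
               tolerance = 1e-8)
  # PCA VE non-increasing
  expect_true(all(diff(fit$ve) <= 1e-12))
  # zero-variance gene contributes nothing
  x2 <- cbind(x, Gz = rep(3, 12))
  expect_equal(unname(variance_explained(x2, fit$scores)$raw),
               unname(variance_explained(x, fit$scores)$raw), tolerance = 1e-12)
  expect_error(variance_explained(x, cbind(fit$scores, fit$scores[, 1])),
               class = "cortexcomp_invalid_argument")
})

test_that("sign alignment is idempotent and follows the reference", {
  x <- rand_matrix(15, 20, seed = 9)
  fit <- fit_components(x, k = 3, method = "pca")
  expect_equal(align_sign(fit)$scores, fit$scores)          # idempotent
  expect_equal(align_sign(fit, reference = fit$scores)$scores, fit$scores)
  flipped <- align_sign(fit, reference = -fit$scores)
  expect_equal(flipped$scores, -fit$scores)
  expect_equal(flipped$weights, -fit$weights)
})

test_that("strongly weighted gene counts match a direct recount", {
  w <- matrix(c(0.6, -0.7, 0.1), 3, 1,
              dimnames = list(c("a", "b", "c"), "C1"))
  expect_equal(unname(strongly_weighted(w, 0.5)$counts), 2L)
  x <- rand_matrix(30, 50, seed = 10)
  fit <- fit_components(x, k = 3, method = "pca")
  sw <- strongly_weighted(fit, 0.3)
  expect_equal(unname(sw$counts),
               unname(colSums(abs(fit$weights) >= 0.3)))
  expect_error(strongly_weighted(w, 1), class = "cortexcomp_invalid_argument")
})

test_that("PCA and DME extract matched leading components on clean cohorts", {
  atl <- generate_atlas(80, seed = 71)
  coh <- generate_cohort(atl, 4, 800, snr = c(8, 6, 4), missing_frac = 0.1,
                         seed = 72)
  m <- preprocess_cohort(coh$donors, min_donors = 3)
  f_dme <- fit_components(m, k = 3, method = "dme")
  f_pca <- fit_components(m, k = 3, method = "pca")
  expect_true(all(abs_cor_diag(f_dme$scores, f_pca$scores) >= 0.95))
})

test_that("model methods: coef, predict, residuals and summary behave", {
  x <- rand_matrix(25, 40, seed = 12)
  fit <- fit_components(x, k = 3, method = "pca")
  expect_identical(coef(fit), fit$weights)
  # predicting the training data reproduces the score pattern
  pr <- predict(fit, x)
  expect_true(all(abs_cor_diag(pr, fit$scores) > 0.95))
  # residuals are orthogonal to the scores
  res <- residuals(fit)
  expect_lt(max(abs(crossprod(fit$scores, res))), 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.cortex_components")
  expect_equal(nrow(s$table), 3)
})
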