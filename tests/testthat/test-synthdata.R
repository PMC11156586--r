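test_that("generated atlases are unit-norm, distinct, and seed-deterministic", {
  atl <- generate_atlas(100, seed = 1)
  xyz <- atlas_coords(atl)
  expect_equal(nrow(atl), 100)
  expect_true(all(abs(sqrt(rowSums(xyz^2)) - 1) < 1e-9))
  d <- tcrossprod(xyz)
  expect_true(max(d[upper.tri(d)]) < 1 - 1e-9)  # min pairwise angle > 0
  expect_identical(atl, generate_atlas(100, seed = 1))
  expect_false(identical(atlas_coords(generate_atlas(100, seed = 2)), xyz))
  expect_error(generate_atlas(5, seed = 1), class = "cortexcomp_invalid_argument")
})

test_that("cohort generation is deterministic and validates K", {
  atl <- small_atlas()
  a <- generate_cohort(atl, 3, 120, snr = c(4, 2), seed = 9)
  b <- generate_cohort(atl, 3, 120, snr = c(4, 2), seed = 9)
  expect_identical(a$donors[[2]]$values, b$donors[[2]]$values)
  expect_error(generate_cohort(atl, 3, 40, snr = rep(2, 11), seed = 1),
               class = "cortexcomp_invalid_argument")
  expect_error(generate_cohort(atl, 1, 120, snr = 2, seed = 1),
               class = "cortexcomp_invalid_argument")
})

test_that("latent truth is orthogonal, z-scored, and noise-free donors coincide", {
  coh <- small_cohort()
  L <- coh$truth$latent_scores
  cc <- cor(L)
  expect_true(max(abs(cc[upper.tri(cc)])) < 1e-6)
  expect_equal(unname(apply(L, 2, sd)), rep(1, ncol(L)))
  expect_equal(unname(colMeans(L)), rep(0, ncol(L)), tolerance = 1e-9)
  # zero-noise limit: identical donor matrices
  z <- generate_cohort(small_atlas(), 3, 80, snr = c(4, 2), noise_sd = 0,
                       nuisance_sd = 0, donor_offset_sd = 0,
                       missing_frac = 0, seed = 4)
  expect_equal(z$donors[[1]]$values, z$donors[[2]]$values)
  expect_equal(z$donors[[2]]$values, z$donors[[3]]$values)
})

test_that("per-donor missingness follows the configured rate", {
  atl <- generate_atlas(120, seed = 3)
  coh <- generate_cohort(atl, 6, 60, snr = c(3, 2), missing_frac = 0.2,
                         seed = 13)
  miss <- vapply(coh$donors, function(d) length(d$missing), integer(1))
  # binomial(120, 0.2) 99% interval per donor
  lo <- qbinom(0.005, 120, 0.2); hi <- qbinom(0.995, 120, 0.2)
  expect_true(all(miss >= lo & miss <= hi))
})

test_that("empirical per-component SNR matches configuration within 20%", {
  atl <- generate_atlas(150, seed = 5)
  snr <- c(6, 3)
  coh <- generate_cohort(atl, 4, 400, snr = snr, n_nuisance = 0,
                         missing_frac = 0, seed = 17)
  tr <- coh$truth
  signal <- lapply(1:2, function(k)
    tr$amplitude[k] * tr$latent_scores[, k, drop = FALSE] %*%
      t(tr$loadings[, k, drop = FALSE]))
  total_signal <- signal[[1]] + signal[[2]]
  emp <- vapply(coh$donors, function(d) {
    resid <- d$values - total_signal[rownames(d$values), ]
    resid <- sweep(resid, 2, colMeans(resid), "-")  # removes donor offsets
    noise_sd <- sd(as.vector(resid))
    vapply(signal, function(s) sd(as.vector(s)) / noise_sd, numeric(1))
  }, numeric(2))
  expect_true(all(abs(rowMeans(emp) / snr - 1) < 0.2))
})

test_that("single cells honor type proportions, coupling, and determinism", {
  coh <- small_cohort()
  cells <- generate_single_cells(coh$truth, 1000, c(a = 0.5, b = 0.5),
                                 seed = 8)
  n_a <- sum(cells$cell_type == "a")
  expect_true(abs(n_a - 500) < qbinom(0.995, 1000, 0.5) - 500 + 1)
  expect_identical(
    cells$values,
    generate_single_cells(coh$truth, 1000, c(a = 0.5, b = 0.5), seed = 8)$values)
  expect_error(generate_single_cells(coh$truth, 10, numeric(0)),
               class = "cortexcomp_invalid_argument")
  # coupling sd 0 -> within-type gene covariance approximately diagonal
  flat <- generate_single_cells(coh$truth, 400, c(a = 1), coupling_sd = 0,
                                noise_sd = 1, seed = 9)
  cv <- cov(flat$values[, 1:40])
  offd <- abs(cv[upper.tri(cv)])
  expect_lt(mean(offd), 0.1 * mean(diag(cv)))
  # with coupling, genes sharing a component loading co-vary within type
  on <- generate_single_cells(coh$truth, 400, c(a = 1), coupling_sd = 2,
                              noise_sd = 0.5, seed = 9)
  ld <- coh$truth$loadings[, 1]
  top <- names(sort(ld, decreasing = TRUE))[1:5]
  bot <- names(sort(ld))[1:5]
  r_ab <- cor(rowMeans(on$values[, top]), rowMeans(on$values[, bot]))
  expect_lt(r_ab, -0.3)  # anti-covariation of opposite-sign genes
})

test_that("developmental generation respects age bounds and amplitudes", {
  coh <- small_cohort()
  tr <- set_age_amplitude(coh$truth,
                          list(age_amp_constant(4),
                               age_amp_logistic(0, 4, midpoint = 12)))
  expect_equal(age_to_pcd(-0.5), 365.25 * -0.5 + 280)  # 97.375 days, valid
  expect_error(age_to_pcd(-0.9), class = "cortexcomp_invalid_argument")
  expect_error(generate_development(tr, ages = c(2, 45)),
               class = "cortexcomp_invalid_argument")
  expect_error(generate_development(coh$truth, ages = 2),
               class = "cortexcomp_invalid_argument")
  dev <- generate_development(tr, ages = c(1, 5, 20, 30), noise_sd = 0.1,
                              seed = 2)
  expect_setequal(names(dev),
                  c("donor", "age_years", "sex", "region", "gene", "value"))
  # component-2 top genes rise from childhood to adulthood
  ld <- coh$truth$loadings[, 2]
  top <- names(sort(ld, decreasing = TRUE))[1:10]
  young <- dev[dev$age_years == 1 & dev$gene %in% top, "value"]
  adult <- dev[dev$age_years == 30 & dev$gene %in% top, "value"]
  expect_gt(mean(adult), mean(young))
  # constant amplitudes -> no age trend
  tr0 <- set_age_amplitude(coh$truth,
                           list(age_amp_constant(3), age_amp_constant(2)))
  dev0 <- generate_development(tr0, ages = c(1, 5, 20, 30), noise_sd = 0.1,
                               seed = 2)
  mg <- aggregate(value ~ age_years, data = dev0[dev0$gene %in% top, ], mean)
  sl <- summary(lm(value ~ age_years, mg))$coefficients["age_years", ]
  expect_gt(sl["Pr(>|t|)"], 0.05)
})
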