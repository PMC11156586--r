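test_that("srs_normalize matches hand-computed values and degenerate cases", {
  expect_equal(srs_normalize(c(0, 1, 2)), c(0, 0.5, 1))
  expect_equal(srs_normalize(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  # monotone: order preserved
  x <- c(5, -1, 3)
  expect_equal(order(srs_normalize(x)), order(x))
  expect_error(srs_normalize(1), class = "cortexcomp_invalid_argument")
})

test_that("srs_normalize is invariant to positive affine input maps", {
  set.seed(3)
  x <- rnorm(50)
  expect_equal(srs_normalize(2.5 * x + 7), srs_normalize(x), tolerance = 1e-12)
  expect_equal(rank(srs_normalize(-x)), rank(-srs_normalize(x)))
})

test_that("differential stability reproduces hand values", {
  regions <- sprintf("R%02d", 1:6)
  base <- matrix(seq_len(12), 6, 2,
                 dimnames = list(regions, c("G1", "G2")))
  # identical profiles across donors -> DS 1
  d_same <- donors_from_matrices(list(base, base + 5, 2 * base))
  expect_equal(unname(unclass(differential_stability(d_same))), c(1, 1))
  # exactly anti-correlated pair -> DS -1
  flip <- base; flip[, 1] <- rev(base[, 1]); flip[, 2] <- rev(base[, 2])
  d_anti <- donors_from_matrices(list(base, flip))
  expect_equal(unname(unclass(differential_stability(d_anti))), c(-1, -1))
  # three donors with pairwise r = (1, 0, 0) -> DS = 1/3
  set.seed(11)
  a <- rnorm(20); ortho <- residuals(lm(rnorm(20) ~ a))
  m1 <- matrix(a, 20, 1, dimnames = list(sprintf("R%02d", 1:20), "G1"))
  m2 <- m1  # r(m1, m2) = 1
  m3 <- matrix(ortho, 20, 1, dimnames = dimnames(m1))  # r = 0 vs both
  ds <- differential_stability(donors_from_matrices(list(m1, m2, m3)))
  expect_equal(unname(unclass(ds)), 1 / 3, tolerance = 1e-12)
  # constant gene in one donor: that pair excluded, warning raised
  m_const <- m1; m_const[, 1] <- 5
  expect_warning(
    ds2 <- differential_stability(donors_from_matrices(list(m1, m2, m_const))),
    "undefined")
  expect_equal(unname(unclass(ds2)), 1)
})

test_that("DS gene filter keeps top fraction with documented tie-break", {
  ds <- structure(c(G1 = 0.9, G2 = 0.5, G3 = 0.1, G4 = -0.2),
                  class = "differential_stability")
  expect_equal(filter_genes_by_ds(ds, 0.5), c("G1", "G2"))
  expect_equal(filter_genes_by_ds(ds, 1.0), c("G1", "G2", "G3", "G4"))
  tie <- structure(c(G1 = 0.5, G2 = 0.5, G3 = 0.1, G4 = -0.2),
                   class = "differential_stability")
  expect_equal(filter_genes_by_ds(tie, 0.5), c("G1", "G2"))
  tie2 <- structure(c(G4 = 0.1, G3 = 0.5, G2 = 0.5, G1 = -0.2),
                    class = "differential_stability")
  expect_equal(sort(filter_genes_by_ds(tie2, 0.5)), c("G2", "G3"))
  expect_error(filter_genes_by_ds(ds, 0), class = "cortexcomp_invalid_argument")
})

test_that("DS decreases with added donor noise (rank test over genes)", {
  atl <- small_atlas()
  noisy <- generate_cohort(atl, 4, 200, snr = c(5, 3), n_nuisance = 0,
                           prop_noisy_genes = 0.5, noisy_gene_factor = 6,
                           missing_frac = 0, seed = 31)
  ds <- differential_stability(noisy$donors)
  fac <- noisy$truth$gene_noise_factor
  expect_gt(median(ds[fac == 1]), median(ds[fac > 1]))
  expect_lt(suppressWarnings(cor(fac, unclass(ds), method = "spearman")), -0.5)
})

test_that("region coverage filter thresholds donor counts", {
  regions <- sprintf("R%02d", 1:10)
  mats <- lapply(1:6, function(i) {
    keep <- regions[seq_len(10 - i)]  # donor i misses the last i regions
    matrix(rnorm(length(keep) * 2), length(keep), 2,
           dimnames = list(keep, c("G1", "G2")))
  })
  donors <- donors_from_matrices(mats, all_regions = regions)
  # region R07 present in donors 1-3 only (3 of 6): kept at min 3
  expect_true("R07" %in% filter_regions_by_coverage(donors, 3))
  # region R05 present in 5 donors; R08 in 2 -> dropped at min 3
  expect_false("R08" %in% filter_regions_by_coverage(donors, 3))
  expect_equal(filter_regions_by_coverage(donors, 1), regions[1:9])
  expect_equal(filter_regions_by_coverage(donors, 6), regions[1:4])
  expect_error(filter_regions_by_coverage(donors, 7),
               class = "cortexcomp_invalid_argument")
  # disjoint donor coverage: no region reaches the threshold
  disj <- donors_from_matrices(
    list(matrix(rnorm(10), 5, 2, dimnames = list(regions[1:5], c("G1", "G2"))),
         matrix(rnorm(10), 5, 2, dimnames = list(regions[6:10], c("G1", "G2")))),
    all_regions = regions)
  expect_error(filter_regions_by_coverage(disj, 2),
               class = "cortexcomp_empty_result")
})

test_that("probe intensity filter pools samples across donors", {
  coh <- generate_cohort(small_atlas(), 3, 60, snr = c(4, 2),
                         probe_expansion = TRUE, missing_frac = 0,
                         seed = 23)
  above <- do.call(cbind, lapply(coh$donors, function(d)
    d$probes$above_background))
  frac <- rowMeans(above)
  kept <- rownames(filter_probes_by_intensity(coh$donors, 0.5)[[1]]$probes$values)
  expect_setequal(kept, names(frac)[frac >= 0.5])
  # threshold 0 keeps everything
  all_kept <- filter_probes_by_intensity(coh$donors, 0)[[1]]$probes$values
  expect_equal(nrow(all_kept), nrow(coh$donors[[1]]$probes$values))
  expect_error(filter_probes_by_intensity(coh$donors, 1.01),
               class = "cortexcomp_empty_result")
})

test_that("probe aggregation picks the most stable probe with id tie-break", {
  regions <- sprintf("R%02d", 1:12)
  set.seed(5)
  profile <- rnorm(12)
  build_donor <- function(noise_bad) {
    pv <- rbind(GA_p1 = profile + rnorm(12, 0, 0.01),
                GA_p2 = rnorm(12, 0, noise_bad),  # unstable probe
                GB_p1 = rnorm(12))                # single-probe gene
    colnames(pv) <- paste0("S_", regions)
    list(values = pv,
         probe_gene = c(GA_p1 = "GA", GA_p2 = "GA", GB_p1 = "GB"),
         sample_region = setNames(regions, colnames(pv)),
         above_background = matrix(TRUE, 3, 12, dimnames = dimnames(pv)))
  }
  donors <- lapply(1:2, function(i) {
    d <- donor_expression(paste0("d", i),
                          matrix(0, 12, 1, dimnames = list(regions, "X")),
                          regions)
    d$probes <- build_donor(1)
    d
  })
  agg <- aggregate_probes_to_genes(donors)
  expect_setequal(colnames(agg[[1]]$values), c("GA", "GB"))
  # GA follows the stable probe profile
  expect_gt(cor(agg[[1]]$values[regions, "GA"], profile), 0.99)
  # exact tie in mean r -> lowest probe id: duplicate stable probes
  donors_tie <- lapply(donors, function(d) {
    d$probes$values["GA_p2", ] <- d$probes$values["GA_p1", ]
    d
  })
  agg_tie <- aggregate_probes_to_genes(donors_tie)
  expect_equal(agg_tie[[1]]$values[regions, "GA"],
               setNames(donors_tie[[1]]$probes$values["GA_p1", paste0("S_", regions)],
                        regions))
})

test_that("group matrix assembly averages donors and fills missing regions", {
  regions <- sprintf("R%02d", 1:8)
  m1 <- matrix(rnorm(16), 8, 2, dimnames = list(regions, c("G1", "G2")))
  # single donor, no normalization: identity
  one <- assemble_group_matrix(donors_from_matrices(list(m1)),
                               normalize = FALSE)
  expect_equal(unclass(one)[regions, ], m1, ignore_attr = TRUE)
  # two donors, one missing a region: that row equals the other donor
  m2 <- matrix(rnorm(14), 7, 2, dimnames = list(regions[-3], c("G1", "G2")))
  two <- assemble_group_matrix(
    donors_from_matrices(list(m1, m2), all_regions = regions),
    normalize = FALSE)
  expect_equal(two["R03", ], m1["R03", ])
  expect_equal(two["R01", ], (m1["R01", ] + m2["R01", ]) / 2)
  # region covered by no donor -> assembly error
  expect_error(
    assemble_group_matrix(donors_from_matrices(list(m2), all_regions = regions),
                          regions = regions),
    class = "cortexcomp_invalid_argument")
  # full chain is deterministic
  coh <- small_cohort()
  expect_identical(preprocess_cohort(coh$donors), preprocess_cohort(coh$donors))
})
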