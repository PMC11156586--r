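# cortexcomp

Spatial components of cortical gene expression, with an honest answer to
the question that matters most about them: **do they generalize across
donors?**

Multi-donor transcriptomic atlases of the human cortex (a few postmortem
brains, hundreds of cortical regions, ~20,000 genes) consistently show a
dominant spatial component of gene expression tracking the
sensorimotor-to-association hierarchy. Whether *higher-order* components
are reproducible biology or donor noise depends entirely on processing
choices. `cortexcomp` implements the full pipeline that makes that
question testable, for analysts working with regional expression matrices
(atlas-derived or synthetic):

- **Preprocessing** — probe intensity filtering and stability-based probe
  aggregation, scaled-robust-sigmoid (SRS) normalization per sample and per
  gene, differential-stability (DS) gene filtering, donor-coverage region
  filtering, donor averaging.
- **Decomposition** — `fit_components()`, a classed model fit by PCA or
  diffusion map embedding (DME; normalized-angle kernel
  `1 - acos(cos_sim)/pi`, anisotropic normalization with alpha = 1,
  diffusion time 0), with per-gene weights `u_g = cor(x_g, C_i)` and
  variance explained `VE_i = (V_{i-1} - V_i)/V_0` from sequential
  regression. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
  `residuals`.
- **Generalizability** — the donor-triplet statistic *g*: run the whole
  pipeline independently on each side of all disjoint donor half-splits
  (10 pairs for 6 donors), greedily match the sides' components, and take
  the median absolute correlation per rank; plus the DS x coverage grid
  search with Pareto reporting.
- **Enrichment** — aggregate-fold-change permutation tests on component
  weights, Fisher/hypergeometric overlap tests, consensus gene lists,
  BH-FDR.
- **Spatial statistics** — spin-rotation null models for parcellated
  spherical maps, spin-aware correlation tests, Moran's I, class ANOVA and
  per-class z-scores against spins.
- **Projection** — single-cell scoring of positively/negatively weighted
  genes and their intracellular coupling, consistency of components in
  external regional datasets (e.g. age windows of a developmental atlas),
  and penalized B-spline developmental trajectories (12 cubic basis
  functions over log10 post-conception days) averaged by gene-weight
  decile.
- **Synthetic cohorts** — `generate_atlas()`, `generate_cohort()`,
  `generate_single_cells()`, `generate_development()`: multi-donor data
  with known latent components, per-component SNR, donor-individual
  spatial structure, region dropout, probe redundancy, cell-level coupling
  and age-phased amplitudes, so every stage above is testable with ground
  truth.

See `vignettes/cortical-components.Rmd` for the model, the design
decisions, and the generator's realism anchors and limits.

## Worked example

Six synthetic donors sharing three latent spatial components (SNR 8/4/2)
on a 120-parcel spherical atlas:

```r
library(cortexcomp)

atlas  <- generate_atlas(120, seed = 1)
cohort <- generate_cohort(atlas, n_donors = 6, n_genes = 2000,
                          snr = c(8, 4, 2), seed = 11)
cohort
#> <synthetic_cohort> 6 donors, 120 parcels, 2000 genes, K = 3 (snr 8/4/2)

mat <- preprocess_cohort(cohort$donors, ds_fraction = 0.5, min_donors = 3)
dim(mat)   # regions sampled by >= 3 donors x top-50% stable genes
#> [1]  115 1000

fit <- fit_components(mat, k = 5, method = "dme")
summary(fit)
#> Component summary (DME; strong = |r| >= 0.5)
#>  component      ve n_strong max_abs_weight
#>         C1 0.56839      840          0.973
#>         C2 0.15817      279          0.915
#>         C3 0.05271       41          0.776
#>         C4 0.00647        0          0.311
#>         C5 0.00547        0          0.250

rep_t <- generalizability(cohort$donors)
rep_t
#> <triplet_report> 10/10 disjoint splits
#>   g: C1 0.98, C2 0.87, C3 0.61, C4 0.47, C5 0.34

truth <- cohort$truth$latent_scores[rownames(fit$scores), ]
round(abs(diag(cor(fit$scores[, 1:3], truth))), 3)
#> [1] 0.962 0.967 0.900
```

Reading the numbers: the three injected components are recovered with
|r| = 0.96/0.97/0.90 against ground truth; variance explained and the
count of strongly weighted genes (|u| >= 0.5) fall steeply over ranks;
and the triplet statistic *g* separates the three real components
(0.98/0.87/0.61) from the post-signal ranks. The rank-4 value (0.47)
rather than a pure-noise ~0.08 is a real phenomenon — a deterministic
"echo" of the dominant component that survives sigmoid normalization and
embedding curvature — discussed in the vignette.

Downstream, `afc_enrichment()` tests gene sets against the weights,
`spin_correlation_test()` and `class_zscores()` give spatially-aware
significance for map comparisons, `score_cells()` /
`coupling_correlation()` quantify intracellular coupling of a component's
two poles, and `external_consistency()` / `fit_trajectories()` /
`decile_curves()` trace components through development.

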