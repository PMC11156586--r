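#' Score single cells on component gene weights
#'
#' For every component, each cell's expression is summarized separately over
#' the positively and negatively weighted genes.  The default convention is
#' a weighted average (dot product divided by the summed absolute weight of
#' the genes used), so that a score is on the scale of expression and
#' independent of gene-set size; for negative weights the magnitudes |u-|
#' are used, so that latent coupling appears as a *negative* correlation
#' between the s+ and s- scores.  The raw dot product (s- weighted by the
#' signed u-) is available with `convention = "dot"`.
#'
#' @param cells cell x gene expression matrix (or a `synthetic_cells`).
#' @param weights gene x K weight matrix (or `cortex_components` fit); only
#'   the gene intersection is used (>= 50 genes required).
#' @param convention `"average"` (default) or `"dot"`.
#' @param min_genes minimum gene intersection (default 50).
#' @return Object of class `cell_scores`: list with `pos` and `neg`
#'   (cell x K score matrices), `convention`, `cell_type` (if supplied on
#'   the input).
#' @export
score_cells <- function(cells, weights, convention = c("average", "dot"),
                        min_genes = 50L) {
  convention <- match.arg(convention)
  cell_type <- NULL
  if (inherits(cells, "synthetic_cells")) {
    cell_type <- cells$cell_type; cells <- cells$values
  }
  if (inherits(weights, "cortex_components")) weights <- weights$weights
  shared <- intersect(colnames(cells), rownames(weights))
  if (length(shared) < min_genes)
    stop_invalid("gene intersection below ", min_genes)
  e <- as.matrix(cells)[, shared, drop = FALSE]
  w <- weights[shared, , drop = FALSE]
  k <- ncol(w)
  pos <- matrix(0, nrow(e), k); neg <- matrix(0, nrow(e), k)
  for (i in seq_len(k)) {
    up <- pmax(w[, i], 0); un <- pmin(w[, i], 0)
    if (all(up == 0) || all(un == 0))
      stop_invalid("component ", i, " has an empty positive or negative gene set")
    pos[, i] <- as.vector(e %*% up)
    if (convention == "average") {
      pos[, i] <- pos[, i] / sum(up)
      neg[, i] <- as.vector(e %*% (-un)) / sum(-un)  # weighted avg with |u-|
    } else {
      neg[, i] <- as.vector(e %*% un)
    }
  }
  dimnames(pos) <- dimnames(neg) <- list(rownames(e), colnames(w))
  structure(list(pos = pos, neg = neg, convention = convention,
                 cell_type = cell_type),
            class = "cell_scores")
}

#' Coupling of positive and negative component scores across cells
#'
#' Pearson correlation between the positive-gene and negative-gene scores of
#' each component, within each cell-type group (or over all cells), with a
#' seeded bootstrap confidence interval.  Groups with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param scores a [score_cells()] result.
#' @param group_by `"cell_type"` (default, if labels are available) or
#'   `"all"`.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param conf CI level.
#' @param seed integer seed.
#' @return Data frame: `group`, `component`, `n`, `r`, `ci_lo`, `ci_hi`.
#' @export
coupling_correlation <- function(scores, group_by = c("cell_type", "all"),
                                 n_boot = 1000L, conf = 0.95, seed = 1L) {
  group_by <- match.arg(group_by)
  groups <- if (group_by == "cell_type" && !is.null(scores$cell_type))
    as.character(scores$cell_type) else rep("all", nrow(scores$pos))
  comps <- colnames(scores$pos)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- list()
    for (gr in unique(groups)) {
      idx <- which(groups == gr)
      if (length(idx) < 3L) {
        warning("group ", gr, " has fewer than 3 cells; skipped")
        next
      }
      for (ci in comps) {
        sp <- scores$pos[idx, ci]; sn <- scores$neg[idx, ci]
        r <- cor(sp, sn)
        bs <- vapply(seq_len(n_boot), function(b) {
          j <- sample.int(length(idx), replace = TRUE)
          suppressWarnings(cor(sp[j], sn[j]))
        }, numeric(1))
        qs <- quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(group = gr, component = ci, n = length(idx), r = r,
                     ci_lo = qs[1], ci_hi = qs[2])
      }
    }
    do.call(rbind, rows)
  })
}

#' Consistency of components in an external regional dataset
#'
#' Projects component gene weights onto an external region x gene expression
#' table and correlates the resulting regional scores with matched reference
#' scores.  Each gene is z-normalized over regions within each external
#' donor; donors are then averaged (e.g. within an age window); the external
#' score of region j on component i is the dot product of its expression
#' vector with the component's gene weights.
#'
#' @param external either a region x gene matrix (one donor / pre-averaged)
#'   or a long data frame with columns `donor`, `region`, `gene`, `value`.
#' @param weights gene x K weight matrix or `cortex_components` fit.
#' @param reference_scores region x K matrix of reference component scores
#'   (row names matched to external regions, >= 3 shared).
#' @param region_map optional named character vector translating external
#'   region names to reference region names.
#' @return List with `r` (per-component Pearson correlation), `scores`
#'   (external region x K scores) and `regions` (matched region ids).
#' @export
external_consistency <- function(external, weights, reference_scores,
                                 region_map = NULL) {
  if (inherits(weights, "cortex_components")) weights <- weights$weights
  if (is.data.frame(external)) {
    zs <- lapply(split(external, external$donor), function(d) {
      m <- as.matrix(unclass(stats::xtabs(value ~ region + gene, data = d)))
      zscore_cols(m)                         # region x gene, z per gene
    })
    regs <- rownames(zs[[1]]); gens <- colnames(zs[[1]])
    ext <- Reduce(`+`, lapply(zs, function(z) z[regs, gens, drop = FALSE]))
    ext <- ext / length(zs)
  } else {
    ext <- zscore_cols(as.matrix(external))  # z per gene over regions
  }
  if (!is.null(region_map)) rownames(ext) <- region_map[rownames(ext)]
  shared_g <- intersect(colnames(ext), rownames(weights))
  if (length(shared_g) < 2L) stop_invalid("too few shared genes")
  y <- ext[, shared_g, drop = FALSE] %*% weights[shared_g, , drop = FALSE]
  shared_r <- intersect(rownames(y), rownames(reference_scores))
  if (length(shared_r) < 3L) stop_invalid("fewer than 3 matched regions")
  r <- vapply(seq_len(ncol(y)), function(i)
    cor(y[shared_r, i], reference_scores[shared_r, i]), numeric(1))
  names(r) <- colnames(weights)
  list(r = r, scores = y, regions = shared_r)
}

# shared design machinery for trajectory fits: cubic B-spline basis on
# log10 post-conception days plus additive sex and region intercepts, with a
# squared-second-difference penalty (weight `penalty`) on spline coefficients
trajectory_design <- function(age_years, sex, region, df = 12L, degree = 3L,
                              age_range = NULL) {
  lpd <- log10(age_to_pcd(age_years))
  rng <- if (is.null(age_range)) range(lpd) else log10(age_to_pcd(age_range))
  basis <- splines::bs(lpd, df = df, degree = degree, Boundary.knots = rng)
  sex <- as.factor(sex); region <- as.factor(region)
  xs <- if (nlevels(sex) > 1L)
    stats::model.matrix(~ sex)[, -1L, drop = FALSE] else NULL
  xr <- if (nlevels(region) > 1L)
    stats::model.matrix(~ region)[, -1L, drop = FALSE] else NULL
  x <- cbind(`(Intercept)` = 1, basis, xs, xr)
  d2 <- diff(diag(df), differences = 2)
  pen <- matrix(0, ncol(x), ncol(x))
  pen[2:(df + 1L), 2:(df + 1L)] <- crossprod(d2)
  list(x = x, penalty = pen, basis_cols = 2:(df + 1L), boundary = rng,
       df = df, degree = degree)
}

#' Fit penalized B-spline developmental trajectories
#'
#' Models expression as a function of log10 post-conception days
#' (`days = 365.25 * years + 280`) with a cubic B-spline basis of `df`
#' functions, additive sex and region intercepts, and a ridge-type
#' squared-second-difference penalty on the spline coefficients
#' (weight `penalty`, default 1), fitted by penalized least squares.
#' `fit_trajectories()` fits many genes at once against the same design
#' (one linear solve); `fit_trajectory()` is the single-gene interface.
#'
#' @param expr long data frame with columns `age_years`, `sex`, `region`,
#'   `value` (single gene), needing >= 20 rows spanning >= 3 distinct ages.
#' @param df number of B-spline basis functions (default 12).
#' @param degree spline degree (default 3).
#' @param penalty smoothing penalty weight (default 1).
#' @param age_grid ages (years) at which to evaluate fitted curves; default
#'   64 points log-spaced over the observed range.
#' @return Object of class `trajectory_fit`: list with `coef`, `curve`
#'   (fitted values on `age_grid`, averaged over sex and region), `age_grid`
#'   and the design metadata.
#' @export
fit_trajectory <- function(expr, df = 12L, degree = 3L, penalty = 1,
                           age_grid = NULL) {
  fits <- fit_trajectories(
    expr[, c("age_years", "sex", "region")],
    matrix(expr$value, ncol = 1, dimnames = list(NULL, "gene")),
    df = df, degree = degree, penalty = penalty, age_grid = age_grid)
  structure(list(coef = fits$coef[, 1], curve = fits$curves[, 1],
                 age_grid = fits$age_grid, df = df, degree = degree,
                 penalty = penalty),
            class = "trajectory_fit")
}

#' @rdname fit_trajectory
#' @param meta data frame with `age_years`, `sex`, `region` (one row per
#'   observation).
#' @param values observation x gene matrix of expression values.
#' @export
fit_trajectories <- function(meta, values, df = 12L, degree = 3L,
                             penalty = 1, age_grid = NULL) {
  values <- as.matrix(values)
  if (nrow(meta) < 20L) stop_invalid("need >= 20 observations")
  if (length(unique(meta$age_years)) < 3L)
    stop_invalid("need >= 3 distinct ages")
  des <- trajectory_design(meta$age_years, meta$sex, meta$region,
                           df = df, degree = degree)
  x <- des$x
  xtx <- crossprod(x) + penalty * des$penalty
  beta <- solve(xtx, crossprod(x, values))
  if (is.null(age_grid)) {
    lr <- des$boundary
    age_grid <- (10^seq(lr[1], lr[2], length.out = 64) - 280) / 365.25
  }
  gb <- splines::bs(log10(age_to_pcd(age_grid)), df = df, degree = degree,
                    Boundary.knots = des$boundary)
  # covariates at their design means -> curves averaged over sex and region
  other <- setdiff(seq_len(ncol(x)), des$basis_cols)
  xg <- matrix(rep(colMeans(x[, other, drop = FALSE]),
                   each = length(age_grid)), length(age_grid))
  grid_x <- matrix(0, length(age_grid), ncol(x))
  grid_x[, des$basis_cols] <- gb
  grid_x[, other] <- xg
  curves <- grid_x %*% beta
  rownames(curves) <- NULL
  list(coef = beta, curves = curves, age_grid = age_grid, df = df,
       degree = degree, penalty = penalty)
}

#' Pivot a long developmental table to an observation x gene matrix
#'
#' One observation per (donor, region); metadata carries age, sex and
#' region, ready for [fit_trajectories()].
#'
#' @param dev long data frame from [generate_development()] /
#'   [read_development()].
#' @return List with `meta` (data frame: age_years, sex, region) and
#'   `values` (observation x gene matrix).
#' @export
development_matrix <- function(dev) {
  key <- paste(dev$donor, dev$region, sep = "\r")
  sp <- split(seq_len(nrow(dev)), key)
  genes <- unique(dev$gene)
  vals <- matrix(NA_real_, length(sp), length(genes),
                 dimnames = list(NULL, genes))
  meta <- dev[vapply(sp, `[`, integer(1), 1L),
              c("age_years", "sex", "region")]
  rownames(meta) <- NULL
  for (j in seq_along(sp))
    vals[j, dev$gene[sp[[j]]]] <- dev$value[sp[[j]]]
  if (anyNA(vals)) stop_invalid("incomplete gene coverage per observation")
  list(meta = meta, values = vals)
}

#' Average fitted trajectories within gene-weight deciles
#'
#' Bins genes into deciles of their component weight (ties broken by gene
#' id) and averages the fitted curves pointwise within each decile.
#'
#' @param fits a [fit_trajectories()] result (curves for >= 10 genes).
#' @param weights named numeric vector of gene weights for one component
#'   (names matched to the columns of `fits$curves`).
#' @return List with `curves` (age grid x 10 matrix, decile 1 = lowest
#'   weights), `age_grid`, `decile` (per-gene assignment).
#' @export
decile_curves <- function(fits, weights) {
  genes <- intersect(colnames(fits$curves), names(weights))
  if (length(genes) < 10L) stop_invalid("need fits for >= 10 genes")
  w <- weights[genes]
  ord <- order(w, genes)                   # weight asc, ties by gene id
  dec <- integer(length(genes))
  dec[ord] <- ceiling(seq_along(genes) / (length(genes) / 10))
  dec[dec > 10L] <- 10L
  curves <- vapply(1:10, function(d) {
    cols <- genes[dec == d]
    if (length(cols) == 0L) return(rep(NA_real_, length(fits$age_grid)))
    rowMeans(fits$curves[, cols, drop = FALSE])
  }, numeric(length(fits$age_grid)))
  colnames(curves) <- paste0("D", 1:10)
  list(curves = curves, age_grid = fits$age_grid,
       decile = setNames(dec, genes))
}
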