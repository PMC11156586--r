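#' Spin-rotation null models for parcellated spherical maps
#'
#' Draws `n_spins` uniform random 3D rotations of the atlas centroids; after
#' each rotation every parcel is reassigned the value of the parcel whose
#' rotated centroid is nearest (great-circle) to its original centroid.
#' Duplicate source parcels are allowed (nearest-centroid matching is not a
#' bijection); the per-spin duplication rate is recorded.
#'
#' @param atlas a [parcel_atlas()] with >= 10 parcels.
#' @param n_spins number of rotations (default 5000).
#' @param seed integer seed; the null set is deterministic given it.
#' @return Object of class `spin_nulls`: `assign` (n_spins x parcels integer
#'   matrix of source-parcel indices), `parcel_id`, `duplication_rate`,
#'   `n_spins`, `seed`.
#' @export
spin_nulls <- function(atlas, n_spins = 5000L, seed = 1L) {
  if (nrow(atlas) < 10L) stop_invalid("atlas must have >= 10 parcels")
  coords <- atlas_coords(atlas)
  p <- nrow(coords)
  with_seed(seed, {
    assign_m <- matrix(0L, n_spins, p)
    for (s in seq_len(n_spins)) {
      rot <- coords %*% t(random_rotation())
      # source j assigned to target i maximizing rotated_j . original_i
      sim <- coords %*% t(rot)             # [target i, source j]
      assign_m[s, ] <- max.col(sim, ties.method = "first")
    }
    dup <- 1 - apply(assign_m, 1, function(z) length(unique(z))) / p
    structure(list(assign = assign_m, parcel_id = rownames(coords),
                   duplication_rate = dup, n_spins = n_spins, seed = seed),
              class = "spin_nulls")
  })
}

#' @export
print.spin_nulls <- function(x, ...) {
  cat("<spin_nulls> ", x$n_spins, " spins over ", length(x$parcel_id),
      " parcels (mean duplication ",
      sprintf("%.1f%%", 100 * mean(x$duplication_rate)), ")\n", sep = "")
  invisible(x)
}

# coerce a map (named vector or data.frame parcel_id,value) to the null
# set's parcel order; unknown parcels are an error, absent parcels become NA
as_brain_map <- function(map, parcel_id) {
  if (is.data.frame(map)) map <- setNames(map$value, map$parcel_id)
  if (is.null(names(map))) {
    if (length(map) != length(parcel_id))
      stop_invalid("unnamed map must match the atlas length")
    names(map) <- parcel_id
  }
  if (!all(names(map) %in% parcel_id))
    stop_invalid("map has parcels not in the atlas")
  out <- setNames(rep(NA_real_, length(parcel_id)), parcel_id)
  out[names(map)] <- map
  out
}

# rows = spins of `a`; Pearson r of each spun a against fixed b (no NAs)
spin_cor_vec <- function(a, b, assign_m) {
  as <- matrix(a[assign_m], nrow(assign_m))
  asc <- as - rowMeans(as)
  bc <- b - mean(b)
  as.vector(asc %*% bc) / (sqrt(rowSums(asc^2)) * sqrt(sum(bc^2)))
}

#' Spin-permutation correlation test between two maps
#'
#' Observed Pearson correlation on the parcels where both maps are present,
#' with a two-sided p value from spinning `map_a` against the fixed `map_b`.
#' Spins that relocate a missing parcel into the support are dropped
#' parcel-wise for that spin.
#'
#' @param map_a,map_b named numeric vectors (or data frames with `parcel_id`
#'   and `value`) on the null set's atlas.
#' @param nulls a [spin_nulls()] object.
#' @param spin_both also spin `map_b` independently (doubles the Monte Carlo
#'   symmetry; default FALSE).
#' @return List with `r`, `p`, `n_parcels`, `null_r`.
#' @export
spin_correlation_test <- function(map_a, map_b, nulls, spin_both = FALSE) {
  a <- as_brain_map(map_a, nulls$parcel_id)
  b <- as_brain_map(map_b, nulls$parcel_id)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop_invalid("fewer than 3 shared parcels")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
    stop_invalid("constant map: correlation undefined")
  r <- cor(a[ok], b[ok])
  am <- nulls$assign
  if (all(ok) && !spin_both) {
    null_r <- spin_cor_vec(a, b, am)
  } else {
    null_r <- vapply(seq_len(nulls$n_spins), function(s) {
      sa <- a[am[s, ]]
      sb <- if (spin_both) b[am[sample.int(nulls$n_spins, 1), ]] else b
      use <- !is.na(sa) & !is.na(sb) & ok
      if (sum(use) < 3L) return(NA_real_)
      cor(sa[use], sb[use])
    }, numeric(1))
    null_r <- null_r[!is.na(null_r)]
  }
  p <- (1 + sum(abs(null_r) >= abs(r))) / (length(null_r) + 1)
  list(r = r, p = p, n_parcels = sum(ok), null_r = null_r)
}

#' Moran's I spatial autocorrelation of a parcellated map
#'
#' `I = (n / sum(W)) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)` with centered
#' values z.  The default weights are inverse great-circle distance between
#' atlas centroids with a zero diagonal; binary k-nearest-neighbor weights
#' or a custom symmetric matrix are also accepted.
#'
#' @param map named numeric vector (or data frame) on the atlas parcels.
#' @param atlas a [parcel_atlas()]; ignored when `W` is supplied.
#' @param weight_scheme `"invdist"` (default) or `"knn"`.
#' @param k neighbors for `"knn"`.
#' @param W optional precomputed weight matrix (zero diagonal).
#' @return Scalar Moran's I.
#' @export
moran_i <- function(map, atlas = NULL, weight_scheme = c("invdist", "knn"),
                    k = 6L, W = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  if (is.null(W)) {
    coords <- atlas_coords(atlas)
    map <- as_brain_map(map, rownames(coords))
    ok <- !is.na(map)
    coords <- coords[ok, , drop = FALSE]; map <- map[ok]
    d <- greatcircle_dist(coords)
    if (weight_scheme == "invdist") {
      W <- 1 / d; diag(W) <- 0
    } else {
      W <- matrix(0, nrow(d), nrow(d))
      for (i in seq_len(nrow(d))) {
        nb <- order(d[i, ])[2:(k + 1L)]
        W[i, nb] <- 1
      }
      W <- pmax(W, t(W))
    }
  } else {
    map <- as.numeric(map)
  }
  n <- length(map)
  if (n < 3L) stop_invalid("need at least 3 parcels")
  z <- map - mean(map)
  if (sum(z^2) == 0) stop_invalid("constant map: Moran's I undefined")
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# one-way F statistics for columns of a values matrix (parcels x draws)
oneway_f <- function(vals, groups) {
  vals <- as.matrix(vals)
  n <- nrow(vals); g <- droplevels(as.factor(groups))
  nc <- as.vector(table(g)); cn <- length(nc)
  gm <- rowsum(vals, g) / nc
  grand <- colMeans(vals)
  ssb <- colSums(nc * sweep(gm, 2, grand, "-")^2)
  sst <- colSums(sweep(vals, 2, grand, "-")^2)
  ssw <- sst - ssb
  (ssb / (cn - 1)) / (ssw / (n - cn))
}

check_classes <- function(classes, ok) {
  g <- droplevels(as.factor(classes[ok]))
  if (nlevels(g) < 2L) stop_invalid("need at least 2 classes")
  if (any(table(g) < 2L)) stop_invalid("every class needs >= 2 parcels")
  g
}

#' One-way ANOVA of class means against spin nulls
#'
#' The observed F statistic for differences in map means across classes is
#' compared with F statistics recomputed on each spun map with the class
#' labels held fixed.
#'
#' @param map named numeric vector (or data frame) on the null set's atlas.
#' @param classes per-parcel class labels (atlas order or named).
#' @param nulls a [spin_nulls()] object.
#' @return List with `F`, `p`, `null_F`.
#' @export
class_anova_spin <- function(map, classes, nulls) {
  a <- as_brain_map(map, nulls$parcel_id)
  if (!is.null(names(classes))) classes <- classes[nulls$parcel_id]
  ok <- !is.na(a)
  g <- check_classes(classes, ok)
  fobs <- oneway_f(a[ok], g)
  spun <- t(matrix(a[t(nulls$assign)], ncol(nulls$assign)))  # spins x parcels
  fnull <- oneway_f(t(spun[, ok, drop = FALSE]), g)
  fnull <- fnull[is.finite(fnull)]
  list(F = fobs, p = (1 + sum(fnull >= fobs)) / (length(fnull) + 1),
       null_F = fnull)
}

#' Per-class mean z-scores against spin nulls
#'
#' For each class, the observed mean map value is normalized by the mean and
#' sd of the class means of the spun maps; two-sided p values come from the
#' null percentile and are BH-FDR corrected across classes.
#'
#' @inheritParams class_anova_spin
#' @return Data frame: `class`, `n`, `mean`, `null_mean`, `null_sd`, `z`,
#'   `p`, `q`.
#' @export
class_zscores <- function(map, classes, nulls) {
  a <- as_brain_map(map, nulls$parcel_id)
  if (!is.null(names(classes))) classes <- classes[nulls$parcel_id]
  ok <- !is.na(a)
  g <- droplevels(as.factor(classes[ok]))
  if (any(table(g) < 2L)) stop_invalid("every class needs >= 2 parcels")
  spun <- matrix(a[nulls$assign], nrow(nulls$assign))[, ok, drop = FALSE]
  nc <- as.vector(table(g))
  null_means <- t(rowsum(t(spun), g) / nc)     # spins x classes
  obs <- as.vector(rowsum(a[ok], g) / nc)
  mu <- colMeans(null_means); sdv <- apply(null_means, 2, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  p <- vapply(seq_along(obs), function(i) {
    if (sdv[i] == 0) return(1)
    (1 + sum(abs(null_means[, i] - mu[i]) >= abs(obs[i] - mu[i]))) /
      (nrow(null_means) + 1)
  }, numeric(1))
  data.frame(class = levels(g), n = nc, mean = obs, null_mean = mu,
             null_sd = sdv, z = z, p = p, q = bh_fdr(p))
}
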