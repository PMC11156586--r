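#' Parcel atlas objects
#'
#' A parcel atlas is the spatial frame for all map-level statistics: a set of
#' uniquely named parcels with unit-sphere centroid coordinates, a hemisphere
#' label and (optionally) a cytoarchitectural class label per parcel.
#'
#' @param parcel_id character vector of unique parcel names.
#' @param coords numeric matrix (parcels x 3) of centroid coordinates; rows
#'   must have unit Euclidean norm to within 1e-9.
#' @param hemisphere single hemisphere label or per-parcel vector.
#' @param class_label optional per-parcel categorical label.
#' @return An object of class `parcel_atlas`: a data frame with columns
#'   `parcel_id`, `x`, `y`, `z`, `hemisphere` and optionally `class_label`.
#' @export
parcel_atlas <- function(parcel_id, coords, hemisphere = "L", class_label = NULL) {
  parcel_id <- as.character(parcel_id)
  coords <- as.matrix(coords)
  if (anyDuplicated(parcel_id)) stop_invalid("parcel ids must be unique")
  if (length(parcel_id) < 10L) stop_invalid("an atlas needs at least 10 parcels")
  if (nrow(coords) != length(parcel_id) || ncol(coords) != 3L)
    stop_invalid("coords must be a parcels x 3 matrix")
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop_invalid("centroids must lie on the unit sphere (norm 1 +/- 1e-9)")
  out <- data.frame(parcel_id = parcel_id,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    hemisphere = rep_len(hemisphere, length(parcel_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(class_label)) out$class_label <- as.character(rep_len(class_label, nrow(out)))
  class(out) <- c("parcel_atlas", "data.frame")
  out
}

#' Extract centroid coordinates from an atlas
#' @param atlas a `parcel_atlas`.
#' @return parcels x 3 numeric matrix with parcel ids as row names.
#' @export
atlas_coords <- function(atlas) {
  m <- as.matrix(atlas[, c("x", "y", "z")])
  rownames(m) <- atlas$parcel_id
  m
}

#' Generate a quasi-uniform spherical parcel atlas
#'
#' Places `n_parcels` centroids on the unit sphere with a Fibonacci lattice
#' (quasi-uniform, all pairwise angular distances strictly positive), then
#' applies a random rotation drawn from the seed so different seeds give
#' differently oriented but equally uniform atlases.  Optional class labels
#' partition the parcels into spatially contiguous groups by k-means on the
#' centroids.
#'
#' @param n_parcels number of parcels (>= 10).
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_classes number of contiguous cytoarchitectural classes to label
#'   (0 = no class labels).
#' @return A [parcel_atlas()].
#' @examples
#' atl <- generate_atlas(100, seed = 1)
#' range(sqrt(rowSums(atlas_coords(atl)^2)))
#' @export
generate_atlas <- function(n_parcels, seed = 1L, n_classes = 0L) {
  if (n_parcels < 10L) stop_invalid("n_parcels must be >= 10")
  with_seed(seed, {
    i <- seq_len(n_parcels) - 0.5
    z <- 1 - 2 * i / n_parcels
    r <- sqrt(pmax(0, 1 - z^2))
    golden <- pi * (3 - sqrt(5))
    phi <- golden * (seq_len(n_parcels) - 1)
    xyz <- cbind(r * cos(phi), r * sin(phi), z)
    xyz <- xyz %*% t(random_rotation())
    xyz <- xyz / sqrt(rowSums(xyz^2))
    lab <- NULL
    if (n_classes > 0L) {
      km <- kmeans(xyz, centers = n_classes, nstart = 5)
      lab <- paste0("class", km$cluster)
    }
    parcel_atlas(sprintf("P%03d", seq_len(n_parcels)), xyz,
                 hemisphere = "L", class_label = lab)
  })
}

#' Write / read an atlas as CSV
#' @param atlas a `parcel_atlas`.
#' @param path file path (CSV).
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parcel_atlas(df$parcel_id, as.matrix(df[, c("x", "y", "z")]),
               hemisphere = df$hemisphere,
               class_label = if ("class_label" %in% names(df)) df$class_label else NULL)
}
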