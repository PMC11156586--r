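#' All disjoint half-splits of a donor set
#'
#' For an even number of donors n, every unordered pair (S, complement of S)
#' with |S| = n/2.  Six donors give 10 disjoint triplet pairs (20 triplets,
#' each paired once with its complement).
#'
#' @param donor_ids character vector of donor ids (even length >= 4).
#' @return List of lists, each with elements `a` and `b` (character vectors).
#' @export
split_disjoint <- function(donor_ids) {
  n <- length(donor_ids)
  if (n < 4L || n %% 2L != 0L)
    stop_invalid("need an even number of donors >= 4")
  half <- n %/% 2L
  sets <- combn(donor_ids, half, simplify = FALSE)
  # keep each unordered {S, complement} pair once: anchor on the first donor
  keep <- vapply(sets, function(s) donor_ids[1] %in% s, logical(1))
  lapply(sets[keep], function(s) list(a = s, b = setdiff(donor_ids, s)))
}

# greedy matching on a square |r| matrix: repeatedly take the global
# maximum, record (row, col), delete its row and column; ties broken by
# smallest (row, col) lexicographically
greedy_match_matrix <- function(amat) {
  n <- min(nrow(amat), ncol(amat))
  row <- integer(n); col <- integer(n)
  avail_r <- seq_len(nrow(amat)); avail_c <- seq_len(ncol(amat))
  for (m in seq_len(n)) {
    sub <- amat[avail_r, avail_c, drop = FALSE]
    hits <- which(sub >= max(sub) - 1e-15, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    row[m] <- avail_r[hits[1, 1]]; col[m] <- avail_c[hits[1, 2]]
    avail_r <- setdiff(avail_r, row[m]); avail_c <- setdiff(avail_c, col[m])
  }
  list(row = row, col = col)
}

#' Greedily match components between two fits
#'
#' Computes the `top_k` x `top_k` matrix of absolute Pearson correlations
#' between the two fits' region scores on the shared regions, then
#' repeatedly takes the global maximum, records that pair, and deletes its
#' row and column until all components are matched (greedy, not
#' assignment-optimal).  Ties at the maximum are broken by the smallest
#' (row, column) pair lexicographically.  Matched pairs are ranked by the
#' mean variance explained of the pair.
#'
#' @param set_a,set_b `cortex_components` fits (or lists with `scores` and
#'   `ve`).
#' @param top_k number of leading components to match (default 5).
#' @return Data frame with columns `comp_a`, `comp_b`, `r`, `abs_r`,
#'   `mean_ve` and `rank` (1 = highest mean VE), ordered by rank.
#' @export
match_components <- function(set_a, set_b, top_k = 5L) {
  shared <- intersect(rownames(set_a$scores), rownames(set_b$scores))
  if (length(shared) < 3L) stop_invalid("fewer than 3 shared regions")
  if (ncol(set_a$scores) < top_k || ncol(set_b$scores) < top_k)
    stop_invalid("both fits need at least top_k components")
  sa <- set_a$scores[shared, seq_len(top_k), drop = FALSE]
  sb <- set_b$scores[shared, seq_len(top_k), drop = FALSE]
  rmat <- cor(sa, sb)
  gm <- greedy_match_matrix(abs(rmat))
  pairs <- data.frame(comp_a = gm$row, comp_b = gm$col,
                      r = rmat[cbind(gm$row, gm$col)])
  pairs$abs_r <- abs(pairs$r)
  ve_a <- set_a$ve %||% rep(NA_real_, top_k)
  ve_b <- set_b$ve %||% rep(NA_real_, top_k)
  pairs$mean_ve <- (ve_a[pairs$comp_a] + ve_b[pairs$comp_b]) / 2
  pairs <- pairs[order(-pairs$mean_ve), ]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

#' Triplet-split generalizability of components
#'
#' Runs the full preprocessing + decomposition pipeline independently on
#' each side of every disjoint donor split, greedily matches the two sides'
#' components per pair on their shared regions, ranks matched pairs by mean
#' variance explained, and summarizes each rank's generalizability g as the
#' median absolute correlation across pairs (standard midpoint median for
#' even pair counts).
#'
#' @param donors list of [donor_expression()] (or a `synthetic_cohort`).
#' @param ds_fraction,min_donors,intensity_fraction preprocessing settings
#'   (applied per split side; `min_donors` is capped at the side size).
#' @param method,k,kernel,alpha decomposition settings (see
#'   [fit_components()]); `k` is also the number of components matched.
#' @param min_shared_regions pairs whose sides share fewer regions than this
#'   are skipped with a warning (default 10).
#' @return Object of class `triplet_report`: list with `g` (named vector,
#'   one value per rank), `pairs` (long data frame of every matched pair in
#'   every split) and `splits` (the donor splits used).
#' @export
generalizability <- function(donors, ds_fraction = 0.5, min_donors = 3L,
                             intensity_fraction = 0.5,
                             method = "dme", k = 5L,
                             kernel = "normalized_angle", alpha = 1,
                             min_shared_regions = 10L) {
  if (inherits(donors, "synthetic_cohort")) donors <- donors$donors
  ids <- vapply(donors, function(d) d$donor_id, character(1))
  splits <- split_disjoint(ids)
  side_fit <- function(sub) {
    m <- preprocess_cohort(donors[match(sub, ids)],
                           ds_fraction = ds_fraction,
                           min_donors = min(min_donors, length(sub)),
                           intensity_fraction = intensity_fraction)
    fit_components(m, k = k, method = method, kernel = kernel, alpha = alpha)
  }
  rows <- list(); skipped <- 0L
  for (p in seq_along(splits)) {
    sp <- splits[[p]]
    fa <- try(side_fit(sp$a), silent = TRUE)
    fb <- try(side_fit(sp$b), silent = TRUE)
    if (inherits(fa, "try-error") || inherits(fb, "try-error")) {
      warning("split ", p, " skipped: a side failed to fit"); skipped <- skipped + 1L
      next
    }
    shared <- intersect(rownames(fa$scores), rownames(fb$scores))
    if (length(shared) < min_shared_regions) {
      warning("split ", p, " skipped: only ", length(shared), " shared regions")
      skipped <- skipped + 1L
      next
    }
    mt <- match_components(fa, fb, top_k = k)
    mt$split <- p
    rows[[length(rows) + 1L]] <- mt
  }
  if (length(rows) < length(splits) / 2)
    stop_empty("fewer than 50% of splits usable")
  pairs <- do.call(rbind, rows)
  g <- vapply(seq_len(k), function(rk)
    median(pairs$abs_r[pairs$rank == rk]), numeric(1))
  names(g) <- paste0("C", seq_len(k))
  structure(list(g = g, pairs = pairs, splits = splits,
                 n_skipped = skipped),
            class = "triplet_report")
}

#' @export
print.triplet_report <- function(x, ...) {
  cat("<triplet_report> ", length(x$splits) - x$n_skipped, "/",
      length(x$splits), " disjoint splits\n  g: ",
      paste(sprintf("%s %.2f", names(x$g), x$g), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Grid search over filter parameters
#'
#' Evaluates generalizability over a grid of differential-stability
#' fractions and donor-coverage thresholds, reporting per-cell g values,
#' retained gene and region counts, and the Pareto frontier (cells not
#' dominated on every g component and both retention counts jointly).
#'
#' @param donors list of [donor_expression()] or a `synthetic_cohort`.
#' @param ds_fractions numeric vector of retain fractions to try.
#' @param min_donors_values integer vector of coverage thresholds to try.
#' @param ... further arguments passed to [generalizability()].
#' @return Data frame: one row per grid cell with `ds_fraction`,
#'   `min_donors`, `g_C1..g_Ck`, `n_genes`, `n_regions`, `pareto` and
#'   `default` (the (0.5, 3) cell).
#' @export
grid_search <- function(donors, ds_fractions = c(0.5, 1.0),
                        min_donors_values = 3L, ...) {
  if (inherits(donors, "synthetic_cohort")) donors <- donors$donors
  if (length(ds_fractions) == 0L || length(min_donors_values) == 0L)
    stop_invalid("grids must be non-empty")
  grid <- expand.grid(ds_fraction = ds_fractions,
                      min_donors = min_donors_values)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rep_i <- generalizability(donors, ds_fraction = grid$ds_fraction[i],
                              min_donors = grid$min_donors[i], ...)
    m <- preprocess_cohort(donors, ds_fraction = grid$ds_fraction[i],
                           min_donors = grid$min_donors[i])
    row <- data.frame(ds_fraction = grid$ds_fraction[i],
                      min_donors = grid$min_donors[i])
    for (nm in names(rep_i$g)) row[[paste0("g_", nm)]] <- rep_i$g[[nm]]
    row$n_genes <- ncol(m); row$n_regions <- nrow(m)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  crit <- as.matrix(res[, grep("^g_|^n_", names(res))])
  res$pareto <- vapply(seq_len(nrow(res)), function(i)
    !any(vapply(seq_len(nrow(res)), function(j)
      j != i && all(crit[j, ] >= crit[i, ]) && any(crit[j, ] > crit[i, ]),
      logical(1))), logical(1))
  res$default <- res$ds_fraction == 0.5 & res$min_donors == 3L
  res
}
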