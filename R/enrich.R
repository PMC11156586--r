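#' Gene-set collections
#'
#' A named list of gene-id sets plus the universe (the pipeline's retained
#' genes).  Sets are intersected with the universe before testing; gene ids
#' are matched by exact string comparison after uppercasing.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of universe gene ids.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_invalid("sets must be named")
  universe <- unique(toupper(universe))
  sets <- lapply(sets, function(s) intersect(unique(toupper(s)), universe))
  empty <- vapply(sets, length, integer(1)) == 0L
  structure(list(sets = sets, universe = universe, empty = empty),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets over a universe of ",
      length(x$universe), " genes (", sum(x$empty),
      " empty after intersection)\n", sep = "")
  invisible(x)
}

#' Aggregate-fold-change permutation enrichment
#'
#' For each gene set, the observed statistic is the mean component weight of
#' the set's members; the null distribution is the same statistic under
#' random permutations of the weights across the gene universe.  The
#' two-sided p value is the add-one-corrected fraction of permutations whose
#' deviation from the null mean is at least as large as the observed
#' deviation; z is the observed deviation in null-sd units.  Degenerate
#' cases (empty set after intersection, or a null with zero sd) return
#' p = 1.  q values are Benjamini-Hochberg across the collection.
#'
#' @param weights named numeric vector of gene weights for one component.
#' @param sets a [gene_set_collection()] (its universe should be the names
#'   of `weights`).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return Data frame with one row per set: `set`, `n_genes`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `q`.
#' @export
afc_enrichment <- function(weights, sets, n_perm = 5000L, seed = 1L) {
  names(weights) <- toupper(names(weights))
  universe <- intersect(sets$universe, names(weights))
  w <- weights[universe]
  if (length(w) < 2L) stop_invalid("universe too small")
  res <- with_seed(seed, {
    # one permutation of the weights per row; each set reads its members'
    # positions, which is equivalent to re-sampling set members
    perm_idx <- replicate(n_perm, sample.int(length(w)))
    lapply(names(sets$sets), function(nm) {
      members <- intersect(sets$sets[[nm]], universe)
      m <- length(members)
      if (m == 0L)
        return(data.frame(set = nm, n_genes = 0L, observed = NA_real_,
                          null_mean = NA_real_, null_sd = NA_real_,
                          z = NA_real_, p = 1))
      pos <- match(members, names(w))
      obs <- mean(w[pos])
      nulls <- colMeans(matrix(w[perm_idx[seq_len(m), , drop = FALSE]], m))
      mu <- mean(nulls); sdv <- sd(nulls)
      if (!is.finite(sdv) || sdv == 0)
        return(data.frame(set = nm, n_genes = m, observed = obs,
                          null_mean = mu, null_sd = 0, z = 0, p = 1))
      p <- (1 + sum(abs(nulls - mu) >= abs(obs - mu))) / (n_perm + 1)
      data.frame(set = nm, n_genes = m, observed = obs, null_mean = mu,
                 null_sd = sdv, z = (obs - mu) / sdv, p = p)
    })
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}

#' Fisher's exact overlap enrichment
#'
#' One-sided (enrichment) hypergeometric tail test of the overlap between
#' two gene sets within a universe, with a Haldane-corrected odds ratio when
#' any 2x2 cell is zero.
#'
#' @param set_a,set_b character vectors of gene ids (subsets of `universe`).
#' @param universe character vector of universe gene ids.
#' @return List with `odds_ratio`, `p`, `overlap` and the 2x2 `table`.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop_invalid("empty universe")
  set_a <- intersect(unique(toupper(set_a)), universe)
  set_b <- intersect(unique(toupper(set_b)), universe)
  n <- length(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- n - a - b - c_
  p <- phyper(a - 1, length(set_b), n - length(set_b), length(set_a),
              lower.tail = FALSE)
  or <- if (any(c(a, b, c_, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  list(odds_ratio = or, p = p, overlap = a,
       table = matrix(c(a, b, c_, d), 2,
                      dimnames = list(c("inA", "notA"), c("inB", "notB"))))
}

#' Subset a gene set by component weight sign
#'
#' Keeps members whose weight on the component is strictly positive (or
#' strictly negative); weight exactly 0 is excluded either way.
#'
#' @param set character vector of gene ids.
#' @param weights gene x K weight matrix (or named vector).
#' @param component column name or index (ignored for a vector).
#' @param sign `"positive"` or `"negative"`.
#' @return Character vector (possibly empty, with a message attribute).
#' @export
subset_by_component_sign <- function(set, weights, component = 1L,
                                     sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  w <- if (is.matrix(weights)) weights[, component] else weights
  names(w) <- toupper(names(w))
  set <- toupper(set)
  w <- w[intersect(set, names(w))]
  out <- if (sign == "positive") names(w)[w > 0] else names(w)[w < 0]
  if (length(out) == 0L) attr(out, "flag") <- "empty after sign filter"
  out
}

#' Consensus gene list across studies
#'
#' Genes reported in at least `min_studies` of the supplied study lists.
#'
#' @param study_lists list of character vectors.
#' @param min_studies minimum number of lists a gene must appear in.
#' @return Character vector of consensus genes.
#' @export
consensus_genes <- function(study_lists, min_studies = 2L) {
  if (length(study_lists) < 1L) stop_invalid("need at least one study list")
  tab <- table(unlist(lapply(study_lists, function(s) unique(toupper(s)))))
  sort(names(tab)[tab >= min_studies])
}

#' Benjamini-Hochberg q values
#'
#' @param p numeric vector of p values in [0, 1].
#' @return Step-up adjusted q values, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
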