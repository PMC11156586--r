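#' Fit spatial components of regional gene expression
#'
#' The central model fit of the package: decomposes a donor-averaged
#' region x gene matrix into `k` spatial components by either linear PCA or
#' diffusion map embedding (DME).  For DME, the affinity between two regions
#' is the normalized-angle kernel `1 - acos(cosine_similarity) / pi`
#' (no sparsification), anisotropically normalized with parameter `alpha`
#' (default 1, which removes the influence of sampling density), converted
#' to a Markov operator, and the top non-trivial eigenvectors are taken with
#' the diffusion-time-0 scaling `lambda / (1 - lambda)`.  Rows enter the
#' kernel as given (post-normalization, in [0, 1]) without re-centering.
#'
#' Component region scores are z-scored; per-gene weights are the Pearson
#' correlations of each gene's regional profile with each component's scores;
#' variance explained is the drop in total residual variance when genes are
#' sequentially regressed on the leading components, as a share of total
#' variance (for PCA this equals the eigenvalue share).
#'
#' @param x region x gene numeric matrix (a `region_gene_matrix` from
#'   [preprocess_cohort()], or any matrix with region row names and gene
#'   column names).
#' @param k number of components; `k <= min(R - 1, G)` for PCA and
#'   `k <= R - 2` for DME.
#' @param method `"dme"` (default) or `"pca"`.
#' @param kernel DME affinity kernel: `"normalized_angle"` (default) or raw
#'   `"cosine"` similarity.
#' @param alpha DME anisotropic normalization exponent (default 1).
#' @param diffusion_time 0 (default, `lambda / (1 - lambda)` scaling) or a
#'   positive integer t (`lambda^t` scaling).
#' @param sign_align align component signs so gene-weight skewness is >= 0
#'   (see [align_sign()]); default TRUE.
#' @return An object of class `cortex_components`: list with `scores`
#'   (region x k, z-scored), `weights` (gene x k Pearson r), `ve`
#'   (share of total variance), `ve_raw` (unnormalized variance drops),
#'   `evals` (PCA eigenvalue shares or DME eigenvalues), `method`, `kernel`,
#'   `alpha`, `k`, `x` (the input matrix) and `call`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30 * 40), 30, 40,
#'             dimnames = list(paste0("R", 1:30), paste0("G", 1:40)))
#' fit <- fit_components(x, k = 3, method = "pca")
#' summary(fit)
#' @export
fit_components <- function(x, k = 5L, method = c("dme", "pca"),
                           kernel = c("normalized_angle", "cosine"),
                           alpha = 1, diffusion_time = 0L,
                           sign_align = TRUE) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("R", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("G", seq_len(ncol(x)))
  r <- nrow(x); g <- ncol(x)
  fit <- if (method == "pca") {
    if (k > min(r - 1L, g)) stop_invalid("k must be <= min(R - 1, G) for PCA")
    fit_pca(x, k)
  } else {
    if (k > r - 2L) stop_invalid("k must be <= R - 2 for DME")
    fit_dme(x, k, kernel, alpha, diffusion_time)
  }
  scores <- apply(fit$scores, 2, zscore)
  dimnames(scores) <- list(rownames(x), paste0("C", seq_len(k)))
  weights <- gene_weights(x, scores)
  ve <- variance_explained(x, scores)
  obj <- structure(list(scores = scores, weights = weights,
                        ve = ve$share, ve_raw = ve$raw, evals = fit$evals,
                        embedding = fit$scores, method = method,
                        kernel = if (method == "dme") kernel else NULL,
                        alpha = if (method == "dme") alpha else NULL,
                        k = k, x = x, call = match.call()),
                   class = "cortex_components")
  if (sign_align) obj <- align_sign(obj) else obj
}

fit_pca <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc, nu = k, nv = 0)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = nrow(x))
  list(scores = scores, evals = sv$d^2 / sum(sv$d^2))
}

# normalized-angle (or cosine) affinity between rows
row_affinity <- function(x, kernel) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop_degenerate("zero row in the expression matrix")
  g <- tcrossprod(x / nrm)
  g[g > 1] <- 1; g[g < -1] <- -1
  if (kernel == "normalized_angle") 1 - acos(g) / pi else g
}

fit_dme <- function(x, k, kernel, alpha, diffusion_time) {
  a <- row_affinity(x, kernel)
  off <- a[upper.tri(a)]
  if (max(off) - min(off) < 1e-12)
    stop_degenerate("all rows are identical up to scale; affinity is uniform")
  d <- rowSums(a)
  w <- a / outer(d^alpha, d^alpha)          # anisotropic normalization
  dw <- rowSums(w)
  s <- w / outer(sqrt(dw), sqrt(dw))         # symmetric conjugate of Markov P
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  phi <- es$vectors / sqrt(dw)               # right eigenvectors of P
  # first eigenvector (lambda = 1) is constant: drop it
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; phi <- phi[, ord, drop = FALSE]
  idx <- 2:(k + 1L)
  lam_k <- pmin(lam[idx], 1 - 1e-12)
  scale <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  scores <- phi[, idx, drop = FALSE] * rep(scale, each = nrow(x))
  list(scores = scores, evals = lam_k)
}

#' Per-gene component weights
#'
#' Weight of gene g on component i is the Pearson correlation between the
#' gene's expression across regions and the component's region scores.
#' Zero-variance genes get weight 0 with a warning.
#'
#' @param x region x gene matrix.
#' @param scores region x K score matrix (rows aligned with `x`).
#' @return gene x K matrix of correlations in [-1, 1].
#' @export
gene_weights <- function(x, scores) {
  x <- as.matrix(x); scores <- as.matrix(scores)
  if (nrow(x) != nrow(scores)) stop_invalid("x and scores need a shared region index")
  sdx <- apply(x, 2, sd)
  w <- suppressWarnings(cor(x, scores))
  if (any(sdx == 0)) {
    warning(sum(sdx == 0), " zero-variance gene(s); weight set to 0")
    w[sdx == 0, ] <- 0
  }
  rownames(w) <- colnames(x)
  w
}

#' Variance explained by sequential component regression
#'
#' `V_i` is the total residual variance (summed over genes) after regressing
#' every gene on components 1..i; the variance explained by component i is
#' `VE_i = (V_{i-1} - V_i) / V_0`, a share of the total variance of the
#' matrix.  For PCA scores this reproduces the eigenvalue shares.
#'
#' @param x region x gene matrix.
#' @param scores region x K component scores, column-ordered as extracted.
#' @return List with `share` (`VE_i / V_0`, length K), `raw` (`V_{i-1} - V_i`)
#'   and `v` (the residual-variance sequence `V_0..V_K`).
#' @export
variance_explained <- function(x, scores) {
  x <- as.matrix(x); scores <- as.matrix(scores)
  k <- ncol(scores); r <- nrow(x)
  xc <- sweep(x, 2, colMeans(x), "-")
  qrS <- qr(cbind(1, scores))
  if (qrS$rank < k + 1L) stop_invalid("score columns are collinear")
  q <- qr.Q(qrS)[, -1L, drop = FALSE]  # orthonormal basis of centered scores
  v0 <- sum(xc^2) / (r - 1)
  proj <- crossprod(q, xc)             # k x G
  drops <- rowSums(proj^2) / (r - 1)
  v <- v0 - cumsum(drops)
  list(share = drops / v0, raw = drops, v = c(v0, v))
}

#' Resolve eigenvector sign ambiguity
#'
#' Flips each component's sign so that either (a) its correlation with a
#' supplied reference score column is non-negative, or (b) absent a
#' reference, the skewness of its gene weights is non-negative.  Idempotent.
#'
#' @param object a `cortex_components` fit.
#' @param reference optional region x K matrix of reference scores.
#' @return The fit with signs aligned.
#' @export
align_sign <- function(object, reference = NULL) {
  flip <- vapply(seq_len(object$k), function(i) {
    if (!is.null(reference) && i <= ncol(reference)) {
      r <- cor(object$scores[, i], reference[, i])
      r < 0
    } else {
      w <- object$weights[, i]
      m2 <- mean((w - mean(w))^2)
      skew <- if (m2 == 0) 0 else mean((w - mean(w))^3) / m2^1.5
      skew < 0
    }
  }, logical(1))
  if (any(flip)) {
    object$scores[, flip] <- -object$scores[, flip, drop = FALSE]
    object$weights[, flip] <- -object$weights[, flip, drop = FALSE]
    object$embedding[, flip] <- -object$embedding[, flip, drop = FALSE]
  }
  object
}

#' Strongly weighted genes per component
#'
#' @param weights gene x K weight matrix (or a `cortex_components` fit).
#' @param threshold absolute-correlation cutoff in (0, 1); genes with
#'   `|weight| >= threshold` count as strongly weighted.
#' @return List with `genes` (per-component character vectors) and `counts`.
#' @export
strongly_weighted <- function(weights, threshold = 0.5) {
  if (inherits(weights, "cortex_components")) weights <- weights$weights
  if (threshold <= 0 || threshold >= 1) stop_invalid("threshold must be in (0, 1)")
  sets <- lapply(seq_len(ncol(weights)), function(i)
    rownames(weights)[abs(weights[, i]) >= threshold])
  names(sets) <- colnames(weights)
  list(genes = sets, counts = vapply(sets, length, integer(1)))
}

#' @export
print.cortex_components <- function(x, ...) {
  cat("<cortex_components> ", toupper(x$method), " fit: ", nrow(x$scores),
      " regions x ", nrow(x$weights), " genes, k = ", x$k, "\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%s %.1f%%", colnames(x$scores), 100 * x$ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cortex_components <- function(object, threshold = 0.5, ...) {
  sw <- strongly_weighted(object, threshold)
  out <- data.frame(component = colnames(object$scores),
                    ve = object$ve,
                    n_strong = sw$counts,
                    max_abs_weight = apply(abs(object$weights), 2, max))
  structure(list(table = out, method = object$method, threshold = threshold),
            class = "summary.cortex_components")
}

#' @export
print.summary.cortex_components <- function(x, ...) {
  cat("Component summary (", toupper(x$method), "; strong = |r| >= ",
      x$threshold, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.cortex_components <- function(object, ...) object$weights

#' Project new regional expression onto fitted components
#'
#' Each gene in `newdata` is z-scored across its regions and the resulting
#' matrix is projected onto the fit's gene weights (dot product over the gene
#' intersection), giving a per-region score for each component.
#'
#' @param object a `cortex_components` fit.
#' @param newdata region x gene matrix on (a superset of) the fitted genes.
#' @param ... unused.
#' @return region x K score matrix.
#' @export
predict.cortex_components <- function(object, newdata, ...) {
  shared <- intersect(colnames(newdata), rownames(object$weights))
  if (length(shared) < 2L) stop_invalid("too few shared genes to project")
  z <- zscore_cols(as.matrix(newdata)[, shared, drop = FALSE])
  z %*% object$weights[shared, , drop = FALSE]
}

#' @export
residuals.cortex_components <- function(object, ...) {
  xc <- sweep(object$x, 2, colMeans(object$x), "-")
  q <- qr.Q(qr(cbind(1, object$scores)))[, -1L, drop = FALSE]
  xc - q %*% crossprod(q, xc)
}

#' @export
plot.cortex_components <- function(x, ...) {
  graphics::barplot(100 * x$ve, names.arg = colnames(x$scores),
                    ylab = "variance explained (%)",
                    main = paste(toupper(x$method), "components"), ...)
  invisible(x)
}
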