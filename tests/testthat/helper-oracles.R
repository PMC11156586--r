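# independent reference implementations used to cross-check the package

# dense eigendecomposition oracle for PCA scores and eigenvalue shares
pca_oracle <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x), "-")
  e <- eigen(tcrossprod(xc), symmetric = TRUE)
  list(scores = e$vectors[, seq_len(k), drop = FALSE],
       share = e$values / sum(e$values))
}

# reference diffusion map coded independently of the package: direct
# eigendecomposition of the nonsymmetric Markov operator built from the
# normalized-angle kernel with alpha = 1, diffusion time 0
dme_oracle <- function(x, k) {
  nrm <- sqrt(rowSums(x^2))
  cs <- tcrossprod(x) / outer(nrm, nrm)
  cs[cs > 1] <- 1; cs[cs < -1] <- -1
  a <- 1 - acos(cs) / pi
  d <- rowSums(a)
  w <- a / outer(d, d)
  p <- w / rowSums(w)
  e <- eigen(p)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  vec <- Re(e$vectors)[, ord, drop = FALSE]
  emb <- vec[, 2:(k + 1), drop = FALSE] *
    rep(lam[2:(k + 1)] / (1 - lam[2:(k + 1)]), each = nrow(x))
  apply(emb, 2, function(v) (v - mean(v)) / sd(v))
}

# brute-force hypergeometric enrichment tail (sum over tables with overlap
# at least the observed one)
hyper_tail_oracle <- function(overlap, n_a, n_b, n) {
  ks <- overlap:min(n_a, n_b)
  sum(choose(n_b, ks) * choose(n - n_b, n_a - ks)) / choose(n, n_a)
}

# independent Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

abs_cor_diag <- function(a, b) abs(diag(cor(a, b)))
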