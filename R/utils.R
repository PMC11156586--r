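#' @importFrom stats cor median quantile rnorm runif rbinom var sd setNames
#'   p.adjust phyper prcomp lm coef pf aggregate complete.cases kmeans
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("cortexcomp_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_empty <- function(...) {
  stop(structure(class = c("cortexcomp_empty_result", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("cortexcomp_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate expr with a local RNG state seeded at `seed`; restores global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# z-score a vector; constant input -> zeros
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# column-wise z-score of a matrix
zscore_cols <- function(m) {
  m <- sweep(m, 2, colMeans(m), "-")
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(m, 2, s, "/")
}

# great-circle distance matrix (radians) between unit-vector rows
greatcircle_dist <- function(xyz) {
  g <- tcrossprod(xyz)
  g[g > 1] <- 1; g[g < -1] <- -1
  acos(g)
}

# uniform random 3D rotation matrix (QR of a Gaussian matrix, sign-corrected)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# fast per-column Pearson r between two matrices with matching columns/rows
colwise_cor <- function(a, b) {
  za <- zscore_cols(a); zb <- zscore_cols(b)
  colSums(za * zb) / (nrow(a) - 1)
}
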