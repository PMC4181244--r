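# Internal numerical helpers.

# Draw n vectors from N(0, Sigma) via symmetric eigendecomposition.
# Negative eigenvalues from roundoff are clamped to zero, so positive
# semidefinite covariance matrices (e.g. a polygenic remainder after removing
# fully pleiotropic QTL variance) are accepted.
.rmvn <- function(n, Sigma) {
  p <- nrow(Sigma)
  if (p == 1L)
    return(matrix(rnorm(n, 0, sqrt(max(Sigma[1, 1], 0))), n, 1))
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(rnorm(n * p), n, p)
  z %*% (t(ev$vectors) * sqrt(lam))
}

.isSPD <- function(S, tol = 1e-10) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    isTRUE(all.equal(S, t(S), tolerance = 1e-8)) &&
    all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > tol * nrow(S))
}

# Stable seed derivation: keep every derived seed a valid 32-bit integer.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7907 * k) %% 2147483647)
}
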