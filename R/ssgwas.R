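# ssGWAS: convert GEBV of genotyped animals into per-SNP effects with
# u = D Z' [Z D Z']^-1 a_g, refine the SNP variance weights iteratively
# (GEBV computed once), and derive per-SNP variances u_i^2 * 2 p_i (1 - p_i).
#
# [Z D Z'] is singular whenever markers outnumber animals (and always when
# centering uses observed frequencies), so by default the inverse is taken
# through the same tuned/blended G* used in the mixed model: Z D Z' =
# 2 sum(p(1-p)) mean(d) * G, and G is tuned/blended against A22 exactly as in
# the evaluation.  Fixtures with an invertible Z D Z' may pass A22 = NULL to
# invert it directly.

#' Back-solve SNP effects from GEBV
#'
#' `u = D Z' [Z D Z']^-1 a_g`, linear in the GEBV vector.
#'
#' @param agHat GEBV of the genotyped animals (one trait), in `Z` row order.
#' @param Z centered gene content (animals x SNPs).
#' @param weights per-SNP variance weights d (default 1).
#' @param ZDZtInv optional precomputed inverse of `[Z D Z']` (e.g. the tuned
#'   blended genomic matrix inverse divided by its scaling constant); when
#'   `NULL` the raw `Z D Z'` is formed and solved directly.
#' @return Numeric vector of SNP effects, one per column of `Z`.
#' @export
backsolveSnpEffects <- function(agHat, Z, weights = NULL, ZDZtInv = NULL) {
  Z <- as.matrix(Z)
  if (length(agHat) != nrow(Z))
    stop("length(agHat) != nrow(Z): ", length(agHat), " vs ", nrow(Z))
  m <- ncol(Z)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m)
  if (is.null(ZDZtInv)) {
    Zw <- sweep(Z, 2L, sqrt(weights), "*")
    ZDZt <- tcrossprod(Zw)
    v <- solve(ZDZt, agHat)
  } else {
    v <- as.numeric(ZDZtInv %*% agHat)
  }
  u <- weights * as.numeric(crossprod(Z, v))
  names(u) <- colnames(Z)
  u
}

#' Per-SNP variance of estimated effects
#'
#' `sigma2_i = u_i^2 * 2 * p_i * (1 - p_i)` with `p_i` the observed frequency
#' of the counted allele.
#'
#' @param u SNP effects.
#' @param p allele frequencies in `[0, 1]`.
#' @return Numeric vector of per-SNP variances.
#' @export
snpVariances <- function(u, p) {
  stopifnot(length(u) == length(p), all(p >= 0 & p <= 1))
  u^2 * 2 * p * (1 - p)
}

#' Iterative SNP variance weighting
#'
#' GEBV are computed once; SNP weights are refined: iteration 0 uses `D = I`,
#' iteration k sets `d_i = u_i^2 * 2 p_i (1 - p_i)` from iteration k-1,
#' rescales so `sum(d) = m`, and recomputes `u` by back-solving with the new
#' `D`.  All iterations are retained; the last is the reported one.
#'
#' When `A22` is supplied, each iteration rebuilds the weighted genomic matrix
#' from `Z` and the current `d`, tunes and blends it against `A22` (same
#' procedure as the evaluation), and inverts that; otherwise the raw
#' `Z D Z'` is inverted directly.
#'
#' @param Z centered gene content (animals x SNPs) *or* a
#'   [GenotypeData-class], in which case centering uses `p`.
#' @param agHat GEBV of the genotyped animals (fixed across iterations).
#' @param p allele frequencies of the counted allele.
#' @param nIter number of weight refinements after the `D = I` iteration
#'   (default 3; iterations 0..nIter are returned).
#' @param A22 pedigree relationships of the genotyped animals, or `NULL`.
#' @param blend blending fraction passed to [tuneAndBlendG()].
#' @param map optional marker map (`snp`, `chr`, `pos`) carried into the
#'   result.
#' @return A [SNPEffectSet-class] with all iterations.
#' @export
iterateWeights <- function(Z, agHat, p, nIter = 3L, A22 = NULL,
                           blend = 0.05, map = NULL) {
  if (is(Z, "GenotypeData")) {
    if (is.null(map)) map <- markerMap(Z)
    gm <- genoMatrix(Z)
    Z <- sweep(gm, 2L, 2 * p, "-")
    Z[is.na(Z)] <- 0
  }
  Z <- as.matrix(Z)
  m <- ncol(Z)
  stopifnot(length(p) == m, length(agHat) == nrow(Z))
  if (is.null(map))
    map <- data.frame(snp = if (is.null(colnames(Z)))
                        paste0("snp", seq_len(m)) else colnames(Z),
                      chr = 1L, pos = seq_len(m), stringsAsFactors = FALSE)
  d <- rep(1, m)
  warnedZero <- FALSE
  rows <- vector("list", nIter + 1L)
  for (it in 0:nIter) {
    inv <- NULL
    if (!is.null(A22)) {
      G <- buildG(Z + rep(2 * p, each = nrow(Z)), p = p, weights = d)
      Gstar <- tuneAndBlendG(G, A22, blend = blend)$G
      cc <- 2 * sum(p * (1 - p)) * mean(d)
      inv <- chol2inv(chol(Gstar)) / cc
    }
    u <- backsolveSnpEffects(agHat, Z, weights = d, ZDZtInv = inv)
    v <- snpVariances(u, p)
    rows[[it + 1L]] <- data.frame(iteration = it, snp = map$snp,
                                  chr = map$chr, pos = map$pos,
                                  index = seq_len(m), effect = u,
                                  weight = d, freq = p, variance = v,
                                  stringsAsFactors = FALSE)
    if (it < nIter) {
      if (all(v == 0)) {
        if (!warnedZero)
          warning("all SNP variances zero; weights reset to identity")
        warnedZero <- TRUE
        d <- rep(1, m)
      } else {
        dNew <- pmax(v, 1e-12 * mean(v[v > 0]))  # keep weights positive
        d <- dNew * m / sum(dNew)
      }
    }
  }
  out <- new("SNPEffectSet", data = do.call(rbind, rows))
  validObject(out)
  out
}
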