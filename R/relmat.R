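# Pedigree and genomic relationship matrices and the single-step H inverse.
#
# A is built by the recursive tabular method (small/medium pedigrees and
# oracle use); inbreeding by Meuwissen & Luo's ancestor-accumulation; A^-1 by
# Henderson's rules with inbreeding, assembled as sparse triplets.  G follows
# VanRaden method 1 with optional SNP variance weights; it is tuned to the
# genotyped-subset pedigree relationships (mean and mean diagonal matched to
# A22, compensating for selective genotyping) and blended 0.95/0.05 with A22
# to guarantee invertibility.

#' Inbreeding coefficients (Meuwissen & Luo)
#'
#' @param ped a [Pedigree-class].
#' @return Numeric vector of inbreeding coefficients F in pedigree order.
#' @export
calcInbreeding <- function(ped) {
  s <- ped@sire; d <- ped@dam
  n <- length(s)
  F <- numeric(n)
  # D_j = Mendelian sampling variance scale; unknown-parent F enters as -1
  Fpar <- function(i) ifelse(i == 0L, -1, F[pmax(i, 1L)])
  D <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- 0.5 - 0.25 * (Fpar(s[i]) + Fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) { F[i] <- 0; next }
    # ancestors of i (self included), processed in decreasing index order
    anc <- i
    stack <- i
    seen <- logical(i)
    seen[i] <- TRUE
    while (length(stack)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (p in c(s[j], d[j])) if (p > 0L && !seen[p]) {
        seen[p] <- TRUE; anc <- c(anc, p); stack <- c(stack, p)
      }
    }
    anc <- sort(anc, decreasing = TRUE)
    L[anc] <- 0
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * D[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
    }
    F[i] <- aii - 1
  }
  names(F) <- ped@id
  F
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense recursive construction with inbreeding; intended for pedigrees up to
#' a few thousand animals (it is also the oracle for the sparse inverse).
#'
#' @param ped a [Pedigree-class].
#' @param ids optional subset of animal labels; the returned matrix is the
#'   corresponding submatrix of the full A (e.g. A22 for genotyped ids).
#' @return Dense symmetric matrix with dimnames; attribute `"inbreeding"`
#'   holds the diagonal minus one for the full pedigree.
#' @export
buildA <- function(ped, ids = NULL) {
  n <- length(ped@id)
  if (n > 20000)
    stop("dense tabular A limited to 20000 animals; use buildAInverse/extractA22")
  s <- ped@sire; d <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[si, j]
      if (di > 0L) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  attr(A, "inbreeding") <- diag(A) - 1
  if (!is.null(ids)) {
    stopifnot(all(ids %in% ped@id))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding-corrected Mendelian sampling variances.
#'
#' @param ped a [Pedigree-class].
#' @return Sparse symmetric matrix (`Matrix` package) with animal labels.
#' @export
buildAInverse <- function(ped) {
  n <- length(ped@id)
  s <- ped@sire; d <- ped@dam
  F <- calcInbreeding(ped)
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
  b <- 1 / (0.5 - 0.25 * (Fs + Fd))
  idx <- seq_len(n)
  ii <- c(idx)
  jj <- c(idx)
  xx <- c(b)
  hs <- s > 0L
  if (any(hs)) {
    i <- idx[hs]; p <- s[hs]; v <- b[hs]
    ii <- c(ii, i, p, p); jj <- c(jj, p, i, p)
    xx <- c(xx, -v / 2, -v / 2, v / 4)
  }
  hd <- d > 0L
  if (any(hd)) {
    i <- idx[hd]; p <- d[hd]; v <- b[hd]
    ii <- c(ii, i, p, p); jj <- c(jj, p, i, p)
    xx <- c(xx, -v / 2, -v / 2, v / 4)
  }
  hb <- hs & hd
  if (any(hb)) {
    p1 <- s[hb]; p2 <- d[hb]; v <- b[hb]
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1)
    xx <- c(xx, v / 4, v / 4)
  }
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped@id, ped@id))
  forceSymmetric(Ainv)
}

#' Extract A22 from the sparse A inverse
#'
#' Pedigree relationships among a subset (typically the genotyped animals)
#' without forming the full dense A: columns of A are obtained by sparse
#' Cholesky solves against the inverse (Colleau's indirect method).
#'
#' @param Ainv sparse A inverse from [buildAInverse()].
#' @param ids animal labels (or integer indices) of the subset.
#' @param chunk number of right-hand sides per solve batch.
#' @return Dense symmetric matrix A22 with dimnames.
#' @export
extractA22 <- function(Ainv, ids, chunk = 512L) {
  n <- nrow(Ainv)
  idx <- if (is.character(ids)) match(ids, rownames(Ainv)) else as.integer(ids)
  if (anyNA(idx)) stop("ids not present in Ainv")
  k <- length(idx)
  ch <- Cholesky(forceSymmetric(Ainv), LDL = FALSE)
  A22 <- matrix(0, k, k)
  for (start in seq(1L, k, by = chunk)) {
    cols <- start:min(start + chunk - 1L, k)
    E <- sparseMatrix(i = idx[cols], j = seq_along(cols), x = 1,
                      dims = c(n, length(cols)))
    S <- solve(ch, E, system = "A")
    A22[, cols] <- as.matrix(S[idx, , drop = FALSE])
  }
  A22 <- (A22 + t(A22)) / 2
  nm <- if (is.character(ids)) ids else rownames(Ainv)[idx]
  dimnames(A22) <- list(nm, nm)
  A22
}

#' Genomic relationship matrix (VanRaden, optionally SNP-weighted)
#'
#' `G = M D M' / (2 * sum(p * (1 - p)) * mean(d))` with `M` the gene content
#' centered by `2p` (missing calls imputed to the column mean, i.e. centered
#' zero) and `D = diag(d)` the SNP variance weights; `d = 1` gives VanRaden
#' method 1.
#'
#' @param g a [GenotypeData-class] or animals x SNPs matrix.
#' @param p allele frequencies used for centering and scaling (default:
#'   observed in `g`, "the current population").
#' @param weights per-SNP weights d (default 1).
#' @return Dense symmetric G with animal dimnames.
#' @export
buildG <- function(g, p = NULL, weights = NULL) {
  gm <- if (is(g, "GenotypeData")) genoMatrix(g) else as.matrix(g)
  if (is.null(p)) p <- alleleFrequencies(gm)
  m <- ncol(gm)
  stopifnot(length(p) == m)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights > 0))
  M <- sweep(gm, 2L, 2 * p, "-")
  M[is.na(M)] <- 0    # mean imputation after centering
  denom <- 2 * sum(p * (1 - p)) * mean(weights)
  if (denom <= 0) stop("degenerate allele frequencies: 2*sum(p(1-p)) = 0")
  Mw <- sweep(M, 2L, sqrt(weights), "*")
  G <- tcrossprod(Mw) / denom
  dimnames(G) <- list(rownames(gm), rownames(gm))
  (G + t(G)) / 2
}

#' Tune G to A22 and blend for invertibility
#'
#' Solves `a + b * mean(G) = mean(A22)` and
#' `a + b * mean(diag(G)) = mean(diag(A22))` for scalars (a, b) — putting the
#' genomic matrix on the scale of the pedigree relationships of the genotyped
#' animals, which absorbs the effect of non-random genotyping — then blends
#' `G* = (1 - blend) * (a + b * G) + blend * A22`.
#'
#' @param G,A22 conformable dense matrices over the same animals.
#' @param blend A22 blending fraction (default 0.05).
#' @return List with `G` (the tuned, blended G*), `a`, `b`.
#' @export
tuneAndBlendG <- function(G, A22, blend = 0.05) {
  stopifnot(all(dim(G) == dim(A22)))
  mg <- mean(G); mdg <- mean(diag(G))
  ma <- mean(A22); mda <- mean(diag(A22))
  if (abs(mdg - mg) < 1e-12)
    stop("degenerate tuning system: mean(G) == mean(diag(G)) (",
         signif(mg, 6), "); G carries no diagonal contrast")
  b <- (mda - ma) / (mdg - mg)
  a <- ma - b * mg
  Gt <- a + b * G
  Gstar <- (1 - blend) * Gt + blend * A22
  list(G = Gstar, a = a, b = b)
}

#' Single-step H inverse
#'
#' `H^-1 = A^-1` plus the genotyped-block correction
#' `G*^-1 - A22^-1` added on the genotyped coordinates.
#'
#' @param Ainv sparse A inverse over the full pedigree.
#' @param A22 pedigree relationships of the genotyped animals.
#' @param Gstar blended genomic relationship matrix (invertible).
#' @param genotypedIds labels (or indices) of the genotyped animals in
#'   `Ainv` order; must match the row order of `A22`/`Gstar`.
#' @return Sparse symmetric H inverse.
#' @export
buildHInverse <- function(Ainv, A22, Gstar, genotypedIds) {
  n <- nrow(Ainv)
  idx <- if (is.character(genotypedIds)) match(genotypedIds, rownames(Ainv))
         else as.integer(genotypedIds)
  if (anyNA(idx)) stop("genotyped ids not present in Ainv")
  k <- length(idx)
  if (k == 0) return(forceSymmetric(Ainv))
  stopifnot(nrow(A22) == k, nrow(Gstar) == k)
  Gi <- chol2inv(chol(Gstar))
  A22i <- chol2inv(chol(A22))
  Delta <- Gi - A22i
  blk <- sparseMatrix(i = rep(idx, times = k), j = rep(idx, each = k),
                      x = as.vector(Delta), dims = c(n, n),
                      dimnames = dimnames(Ainv))
  forceSymmetric(Ainv + blk)
}

#' Export a relationship matrix as coordinate-format text
#'
#' Lower-triangle (id_i, id_j, value) rows, the convention of common BLUP
#' tooling.
#'
#' @param M matrix (dense or sparse) with dimnames.
#' @param path output path.
#' @param tol entries with |value| <= tol are omitted.
#' @export
writeCoordinateMatrix <- function(M, path, tol = 0) {
  M <- as(as(M, "generalMatrix"), "TsparseMatrix")
  keep <- M@i >= M@j & abs(M@x) > tol
  d <- data.frame(id_i = rownames(M)[M@i[keep] + 1L],
                  id_j = colnames(M)[M@j[keep] + 1L],
                  value = M@x[keep])
  write.table(d, path, quote = FALSE, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(NULL)
}
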