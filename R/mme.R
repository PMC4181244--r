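# Multi-trait single-step mixed model: Henderson's MME with fixed sex and
# contemporary-group effects per trait, an animal additive effect over the
# whole pedigree with covariance H (x) G0, and a maternal permanent
# environment effect of the dam with covariance I (x) P0.  Missing traits are
# handled record-wise: the residual covariance of each record is restricted
# to its observed traits.  Solved by Jacobi-preconditioned conjugate
# gradients (or a direct sparse solve for fixtures).

#' Model specification for the multi-trait animal model
#'
#' @param traits character, phenotype column names in analysis order.
#' @param G0 additive genetic covariance matrix (traits x traits).
#' @param R0 residual covariance matrix.
#' @param P0 maternal permanent environment covariance; `NULL` drops the
#'   effect.
#' @param fixed fixed-effect columns fitted per trait; the first level of
#'   every factor after the first is dropped, so the model is full rank.
#' @return List of class `ModelSpec`.
#' @export
modelSpec <- function(traits, G0, R0, P0 = NULL, fixed = c("sex", "cg")) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  nT <- length(traits)
  stopifnot(nrow(G0) == nT, nrow(R0) == nT)
  if (!.isSPD(G0)) stop("G0 must be symmetric positive definite")
  if (!.isSPD(R0)) stop("R0 must be symmetric positive definite")
  if (!is.null(P0)) {
    P0 <- as.matrix(P0)
    stopifnot(nrow(P0) == nT)
    ev <- eigen((P0 + t(P0)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10)) stop("P0 must be positive semidefinite")
    if (any(ev <= 1e-12)) stop("P0 must be invertible to be fitted; drop it with P0 = NULL")
  }
  structure(list(traits = traits, G0 = G0, R0 = R0, P0 = P0, fixed = fixed),
            class = "ModelSpec")
}

# residual inverse per missingness pattern
.patternRinv <- function(R0, obs) {
  solve(R0[obs, obs, drop = FALSE])
}

#' Assemble the mixed model equations
#'
#' Equations are ordered effect-major with traits innermost: all fixed-effect
#' levels, then the additive effect of every pedigree animal (genotyped or
#' not, phenotyped or not), then the permanent environment of every dam with
#' recorded offspring.  The relationship-inverse contribution is
#' `relInv (x) solve(G0)` on the additive block — pass `buildHInverse()`
#' output for single-step, or `buildAInverse()` for pedigree BLUP (with no
#' genotyped animals the two are the same system).
#'
#' @param spec a [modelSpec()].
#' @param phen phenotype data.frame: `animal`, the fixed-effect columns, a
#'   `dam` column when P0 is fitted, and one column per trait (NA = missing).
#' @param ped a [Pedigree-class]; all phenotyped animals must be in it.
#' @param relInv sparse relationship inverse over the pedigree (H^-1 or A^-1).
#' @return List of class `MMESystem` with the sparse LHS, RHS and the
#'   equation layout needed to unpack solutions.
#' @export
buildMME <- function(spec, phen, ped, relInv) {
  stopifnot(inherits(spec, "ModelSpec"), is(ped, "Pedigree"))
  ids <- ped@id
  n <- length(ids)
  stopifnot(nrow(relInv) == n)
  aIdx <- match(phen$animal, ids)
  if (anyNA(aIdx))
    stop("phenotyped animals missing from pedigree: ",
         paste(head(phen$animal[is.na(aIdx)], 5), collapse = ", "))
  nT <- length(spec$traits)
  nRec <- nrow(phen)

  # fixed-effect layout: first factor keeps all levels (acts as intercept),
  # later factors drop their first level
  facs <- lapply(seq_along(spec$fixed), function(k) {
    f <- factor(phen[[spec$fixed[k]]])
    if (k > 1 && nlevels(f) > 1) {
      lev <- levels(f)
      list(code = match(as.character(f), lev) - 1L, nlev = length(lev) - 1L,
           labels = lev[-1], name = spec$fixed[k])
    } else if (k > 1) {
      list(code = rep(0L, nRec), nlev = 0L, labels = character(0),
           name = spec$fixed[k])
    } else {
      list(code = as.integer(f), nlev = nlevels(f), labels = levels(f),
           name = spec$fixed[k])
    }
  })
  nlevs <- vapply(facs, `[[`, integer(1), "nlev")
  fixOff <- cumsum(c(0L, nlevs[-length(nlevs)])) * nT
  nFix <- sum(nlevs) * nT
  addOff <- nFix
  usePE <- !is.null(spec$P0)
  if (usePE) {
    if (!"dam" %in% colnames(phen))
      stop("P0 is fitted but phenotype table has no 'dam' column")
    dIdx <- match(as.character(phen$dam), ids)  # NA: unknown dam, no PE term
    peAnimals <- sort(unique(dIdx[!is.na(dIdx)]))
    peMap <- match(dIdx, peAnimals)
    nPE <- length(peAnimals)
  } else {
    peMap <- rep(NA_integer_, nRec); peAnimals <- integer(0); nPE <- 0L
  }
  peOff <- addOff + n * nT
  neq <- nFix + n * nT + nPE * nT

  Y <- as.matrix(phen[, spec$traits, drop = FALSE])
  obs <- !is.na(Y)
  if (!any(obs)) stop("no phenotype records")
  # number observation cells record-major so each record's cells are
  # contiguous (R indexes `obs` column-major)
  ord <- order(row(Y)[obs], col(Y)[obs])
  cellId <- matrix(NA_integer_, nRec, nT)
  cellId[which(obs)[ord]] <- seq_len(sum(obs))
  nCell <- sum(obs)

  recOf <- integer(nCell); trOf <- integer(nCell)
  recOf[cellId[obs]] <- row(Y)[obs]
  trOf[cellId[obs]] <- col(Y)[obs]
  yv <- numeric(nCell)
  yv[cellId[obs]] <- Y[obs]

  # design triplets
  wi <- list(); wj <- list(); wx <- list()
  push <- function(i, j) {
    k <- length(wi) + 1L
    wi[[k]] <<- i; wj[[k]] <<- j; wx[[k]] <<- rep(1, length(i))
  }
  cells <- seq_len(nCell)
  for (k in seq_along(facs)) {
    f <- facs[[k]]
    lv <- f$code[recOf]
    keep <- lv > 0L
    if (any(keep))
      push(cells[keep], fixOff[k] + (lv[keep] - 1L) * nT + trOf[keep])
  }
  push(cells, addOff + (aIdx[recOf] - 1L) * nT + trOf)
  if (usePE) {
    pm <- peMap[recOf]
    keep <- !is.na(pm)
    if (any(keep))
      push(cells[keep], peOff + (pm[keep] - 1L) * nT + trOf[keep])
  }
  W <- sparseMatrix(i = unlist(wi), j = unlist(wj), x = unlist(wx),
                    dims = c(nCell, neq))

  # residual inverse, block per record grouped by missingness pattern
  pat <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  ri <- list(); rj <- list(); rx <- list()
  for (pp in unique(pat)) {
    tr <- as.integer(strsplit(pp, ",")[[1]])
    if (!length(tr)) next
    Rinv <- .patternRinv(spec$R0, tr)
    recs <- which(pat == pp)
    nt <- length(tr)
    g1 <- rep(seq_len(nt), times = nt)
    g2 <- rep(seq_len(nt), each = nt)
    k <- length(ri) + 1L
    ri[[k]] <- as.vector(vapply(recs, function(r) cellId[r, tr][g1],
                                integer(length(g1))))
    rj[[k]] <- as.vector(vapply(recs, function(r) cellId[r, tr][g2],
                                integer(length(g2))))
    rx[[k]] <- rep(as.vector(Rinv), times = length(recs))
  }
  Rin <- sparseMatrix(i = unlist(ri), j = unlist(rj), x = unlist(rx),
                      dims = c(nCell, nCell))

  WtR <- crossprod(W, Rin)
  LHS <- WtR %*% W
  rhs <- as.numeric(WtR %*% yv)

  G0i <- solve(spec$G0)
  Sig <- kronecker(relInv, G0i)
  blocks <- list(Diagonal(nFix, x = rep(0, nFix)), Sig)
  if (usePE && nPE > 0)
    blocks[[3]] <- kronecker(Diagonal(nPE), solve(spec$P0))
  LHS <- LHS + bdiag(blocks)
  LHS <- as(LHS, "CsparseMatrix")

  dg <- Matrix::diag(LHS)
  dead <- which(dg == 0)
  if (length(dead)) {   # unused fixed levels (e.g. a cg level never observed
    LHS <- LHS + sparseMatrix(i = dead, j = dead, x = 1, dims = dim(LHS))
    rhs[dead] <- 0      # for some trait): pin to zero
  }

  structure(list(LHS = LHS, rhs = rhs, spec = spec, ped = ped,
                 layout = list(nT = nT, nFix = nFix, addOff = addOff,
                               peOff = peOff, facs = facs, fixOff = fixOff,
                               peAnimals = peAnimals, neq = neq)),
            class = "MMESystem")
}

# Jacobi-preconditioned conjugate gradient on a sparse SPD system.
.pcg <- function(A, b, tol = 1e-12, maxIter = 5000L) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), iterations = 0L,
                           relres = 0, history = numeric(0)))
  dg <- Matrix::diag(A)
  dg[dg <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / dg
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(maxIter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / nb
    hist <- c(hist, relres)
    if (relres < tol)
      return(list(x = x, iterations = it, relres = relres, history = hist))
    z <- r / dg
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  cond <- structure(class = c("pcgNonConvergence", "error", "condition"),
                    list(message = sprintf(
                      "PCG did not converge in %d iterations (relres %.3e)",
                      maxIter, hist[length(hist)]),
                      call = sys.call(-1), history = hist))
  stop(cond)
}

#' Solve assembled mixed model equations
#'
#' @param system an `MMESystem` from [buildMME()].
#' @param method `"pcg"` (Jacobi-preconditioned conjugate gradient, default)
#'   or `"direct"` (sparse Cholesky, for fixtures).
#' @param tol PCG convergence tolerance on the relative residual.
#' @param maxIter PCG iteration cap; non-convergence is an error carrying the
#'   residual history.
#' @return List of class `MMESolution`: `gebv` (pedigree animals x traits),
#'   `fixed` (data.frame of fixed-effect estimates), `pe` (dam PE estimates
#'   or NULL), `convergence` (iterations, final relative residual, history).
#' @export
solveMME <- function(system, method = c("pcg", "direct"), tol = 1e-12,
                     maxIter = 5000L) {
  method <- match.arg(method)
  if (method == "direct") {
    x <- as.numeric(solve(forceSymmetric(system$LHS), system$rhs))
    conv <- list(iterations = NA_integer_, relres = 0, history = numeric(0))
  } else {
    res <- .pcg(system$LHS, system$rhs, tol = tol, maxIter = maxIter)
    x <- res$x
    conv <- res[c("iterations", "relres", "history")]
  }
  lay <- system$layout
  nT <- lay$nT
  ids <- system$ped@id
  n <- length(ids)
  gebv <- matrix(x[lay$addOff + seq_len(n * nT)], n, nT, byrow = TRUE,
                 dimnames = list(ids, system$spec$traits))
  fixed <- do.call(rbind, lapply(seq_along(lay$facs), function(k) {
    f <- lay$facs[[k]]
    if (f$nlev == 0) return(NULL)
    est <- matrix(x[lay$fixOff[k] + seq_len(f$nlev * nT)], f$nlev, nT,
                  byrow = TRUE)
    data.frame(effect = f$name, level = rep(f$labels, times = nT),
               trait = rep(system$spec$traits, each = f$nlev),
               estimate = as.vector(est), stringsAsFactors = FALSE)
  }))
  pe <- NULL
  if (length(lay$peAnimals)) {
    nPE <- length(lay$peAnimals)
    pe <- matrix(x[lay$peOff + seq_len(nPE * nT)], nPE, nT, byrow = TRUE,
                 dimnames = list(ids[lay$peAnimals], system$spec$traits))
  }
  structure(list(gebv = gebv, fixed = fixed, pe = pe, convergence = conv,
                 solution = x),
            class = "MMESolution")
}

#' Fit the single-step model in one call
#'
#' Convenience wrapper: [buildMME()] + [solveMME()].
#'
#' @inheritParams buildMME
#' @inheritParams solveMME
#' @return An `MMESolution`.
#' @export
fitSSGBLUP <- function(spec, phen, ped, relInv, method = "pcg",
                       tol = 1e-12, maxIter = 5000L) {
  solveMME(buildMME(spec, phen, ped, relInv), method = method, tol = tol,
           maxIter = maxIter)
}
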