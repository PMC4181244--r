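# Mixed model equations: degeneracies, symmetry, the dense normal-equation
# oracle, solver agreement and the pedigree-BLUP limit.

test_that("one record with lambda = 1 gives a zero EBV (mean absorbs it)", {
  ped <- Pedigree(data.frame(animal = "a1", sire = NA, dam = NA))
  phen <- data.frame(animal = "a1", sex = "X", cg = "c", y = 3.7)
  spec <- modelSpec("y", matrix(1), matrix(1))
  fit <- fitSSGBLUP(spec, phen, ped, buildAInverse(ped), method = "direct")
  expect_equal(unname(fit$gebv["a1", "y"]), 0)
  expect_equal(fit$fixed$estimate, 3.7)
})

test_that("unrelated animals with identical records get identical EBVs", {
  ped <- Pedigree(data.frame(animal = c("a", "b", "c"), sire = NA, dam = NA))
  phen <- data.frame(animal = c("a", "b", "c"), sex = "X", cg = "c",
                     y = c(2, 2, 5))
  spec <- modelSpec("y", matrix(0.5), matrix(0.5))
  fit <- fitSSGBLUP(spec, phen, ped, buildAInverse(ped), method = "direct")
  expect_equal(unname(fit$gebv["a", "y"]), unname(fit$gebv["b", "y"]))
  expect_gt(fit$gebv["c", "y"], fit$gebv["a", "y"])
})

# independent dense assembly: explicit per-record loops over observed traits,
# dense kronecker penalty blocks, base solve()
denseMmeOracle <- function(spec, phen, ped, relInv) {
  nT <- length(spec$traits)
  ids <- ped@id
  n <- length(ids)
  sexLev <- levels(factor(phen$sex))
  cgLev <- levels(factor(phen$cg))
  cgLev <- if (length(cgLev) > 1) cgLev[-1] else character(0)
  nFix <- (length(sexLev) + length(cgLev)) * nT
  dams <- sort(unique(match(phen$dam[!is.na(phen$dam) &
                                     phen$dam %in% ids], ids)))
  usePE <- !is.null(spec$P0) && length(dams) > 0
  nPE <- if (usePE) length(dams) else 0
  neq <- nFix + n * nT + nPE * nT
  colOf <- function(r, t) {
    cols <- numeric(0)
    s <- match(phen$sex[r], sexLev)
    cols <- c(cols, (s - 1) * nT + t)
    cpos <- match(phen$cg[r], cgLev)
    if (!is.na(cpos))
      cols <- c(cols, length(sexLev) * nT + (cpos - 1) * nT + t)
    a <- match(phen$animal[r], ids)
    cols <- c(cols, nFix + (a - 1) * nT + t)
    if (usePE && !is.na(phen$dam[r]) && phen$dam[r] %in% ids) {
      d <- match(match(phen$dam[r], ids), dams)
      cols <- c(cols, nFix + n * nT + (d - 1) * nT + t)
    }
    cols
  }
  LHS <- matrix(0, neq, neq)
  rhs <- numeric(neq)
  Y <- as.matrix(phen[, spec$traits, drop = FALSE])
  for (r in seq_len(nrow(phen))) {
    obs <- which(!is.na(Y[r, ]))
    if (!length(obs)) next
    Rinv <- solve(spec$R0[obs, obs, drop = FALSE])
    for (i in seq_along(obs)) {
      ci <- colOf(r, obs[i])
      for (j in seq_along(obs)) {
        cj <- colOf(r, obs[j])
        LHS[ci, cj] <- LHS[ci, cj] + Rinv[i, j]   # all design entries are 1
        rhs[ci] <- rhs[ci] + Rinv[i, j] * Y[r, obs[j]]
      }
    }
  }
  addPen <- kronecker(as.matrix(relInv), solve(spec$G0))
  ai <- nFix + seq_len(n * nT)
  LHS[ai, ai] <- LHS[ai, ai] + addPen
  if (usePE) {
    pi <- nFix + n * nT + seq_len(nPE * nT)
    LHS[pi, pi] <- LHS[pi, pi] + kronecker(diag(nPE), solve(spec$P0))
  }
  dg <- diag(LHS) == 0
  diag(LHS)[dg] <- 1
  rhs[dg] <- 0
  x <- solve(LHS, rhs)
  gebv <- matrix(x[nFix + seq_len(n * nT)], n, nT, byrow = TRUE,
                 dimnames = list(ids, spec$traits))
  list(x = x, gebv = gebv)
}

test_that("sparse assembly matches a dense loop-built oracle (2 traits, PE, missing records)", {
  set.seed(21)
  ped <- randomPedigree(30, nFounders = 10, seed = 21)
  ids <- ped@id
  recorded <- ids[11:30]
  damOf <- pedigreeTable(ped)$dam[match(recorded, ids)]
  phen <- data.frame(animal = recorded,
                     sex = sample(c("M", "F"), 20, TRUE),
                     cg = sample(c("c1", "c2", "c3"), 20, TRUE),
                     dam = damOf,
                     t1 = rnorm(20), t2 = rnorm(20),
                     stringsAsFactors = FALSE)
  phen$t2[sample(20, 6)] <- NA
  G0 <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  R0 <- matrix(c(0.7, 0.2, 0.2, 0.8), 2)
  P0 <- diag(c(0.05, 0.08))
  spec <- modelSpec(c("t1", "t2"), G0, R0, P0)
  relInv <- buildAInverse(ped)
  fit <- fitSSGBLUP(spec, phen, ped, relInv, method = "direct")
  oracle <- denseMmeOracle(spec, phen, ped, relInv)
  expect_lt(max(abs(fit$gebv - oracle$gebv)), 1e-6)
  expect_lt(max(abs(fit$solution - oracle$x)), 1e-6)
})

test_that("PCG agrees with the direct solve and degrades gracefully with loose tol", {
  set.seed(22)
  ped <- randomPedigree(120, nFounders = 30, seed = 22)
  recorded <- ped@id[31:120]
  phen <- data.frame(animal = recorded,
                     sex = sample(c("M", "F"), 90, TRUE),
                     cg = sample(paste0("c", 1:4), 90, TRUE),
                     y = rnorm(90), stringsAsFactors = FALSE)
  spec <- modelSpec("y", matrix(0.3), matrix(0.7))
  sys <- buildMME(spec, phen, ped, buildAInverse(ped))
  expect_gt(length(sys$rhs), 120)     # a ~300-equation scale fixture
  direct <- solveMME(sys, method = "direct")
  pcg <- solveMME(sys, method = "pcg", tol = 1e-12)
  expect_lt(max(abs(pcg$solution - direct$solution)), 1e-8)
  loose <- solveMME(sys, method = "pcg", tol = 1e-4)
  expect_lt(max(abs(loose$solution - direct$solution)), 1e-3)
  # identity system returns the right-hand side
  idSys <- sys
  idSys$LHS <- Matrix::Diagonal(length(sys$rhs))
  idSol <- solveMME(idSys, method = "pcg")
  expect_equal(idSol$solution, sys$rhs, tolerance = 1e-10)
  # non-convergence carries the residual history
  err <- tryCatch(solveMME(sys, method = "pcg", tol = 1e-14, maxIter = 3L),
                  error = function(e) e)
  expect_s3_class(err, "pcgNonConvergence")
  expect_length(err$history, 3)
})

test_that("with no genotyped animals ssGBLUP equals pedigree BLUP; record order is irrelevant", {
  set.seed(23)
  ped <- randomPedigree(60, nFounders = 20, seed = 23)
  recorded <- ped@id[21:60]
  phen <- data.frame(animal = recorded, sex = sample(c("M", "F"), 40, TRUE),
                     cg = "c1", y = rnorm(40), stringsAsFactors = FALSE)
  spec <- modelSpec("y", matrix(0.3), matrix(0.7))
  Ainv <- buildAInverse(ped)
  Hinv <- buildHInverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), character(0))
  a <- fitSSGBLUP(spec, phen, ped, Ainv, method = "direct")
  h <- fitSSGBLUP(spec, phen, ped, Hinv, method = "direct")
  expect_equal(a$gebv, h$gebv)
  perm <- fitSSGBLUP(spec, phen[sample(40), ], ped, Ainv, method = "direct")
  expect_equal(perm$gebv, a$gebv, tolerance = 1e-9)
})

test_that("phenotyped animals must be in the pedigree and GEBV cover everyone", {
  ped <- trioPedigree()
  phen <- data.frame(animal = c("3", "ghost"), sex = "X", cg = "c",
                     y = c(1, 2))
  spec <- modelSpec("y", matrix(1), matrix(1))
  expect_error(buildMME(spec, phen, ped, buildAInverse(ped)),
               "missing from pedigree")
  fit <- fitSSGBLUP(spec, phen[1, ], ped, buildAInverse(ped),
                    method = "direct")
  expect_equal(rownames(fit$gebv), ped@id)   # unphenotyped animals included
})
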