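# Fixtures built in code: small deterministic pedigrees, HWE genotype
# panels, and a scenario-runner used by the stability tests.

# founders 1,2 unrelated; 3 = 1 x 2; 4 = 1 x 2 (full sib of 3); 5 = 1 x 3
# (parent-offspring mating -> F = 0.25)
trioPedigree <- function() {
  Pedigree(data.frame(
    animal = c("1", "2", "3", "4", "5"),
    sire = c(NA, NA, "1", "1", "1"),
    dam = c(NA, NA, "2", "2", "3"),
    generation = c("G0", "G0", "G1", "G1", "G2")))
}

# random pedigree: nFounders base animals, the rest with parents drawn from
# earlier animals (occasionally unknown)
randomPedigree <- function(n, nFounders = 20, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("p%04d", seq_len(n))
  for (i in (nFounders + 1):n) {
    s <- sample(seq_len(i - 1), 2)
    sire[i] <- ids[s[1]]
    if (s[2] != s[1]) dam[i] <- ids[s[2]]
  }
  Pedigree(data.frame(animal = ids, sire = sire, dam = dam,
                      generation = "x"))
}

# HWE genotypes at true frequencies p (centering with these keeps Z Z'
# nonsingular for n < m)
hweGenotypes <- function(n, m, seed = 1, pRange = c(0.2, 0.8)) {
  set.seed(seed)
  p <- runif(m, pRange[1], pRange[2])
  geno <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                 dimnames = list(sprintf("a%04d", seq_len(n)),
                                 sprintf("s%04d", seq_len(m))))
  list(geno = geno, p = p)
}

# fully genotyped, unrelated-founder GBLUP fixture with marker-simulated
# breeding values: the classical GBLUP / SNP-BLUP equivalence world
gblupFixture <- function(n = 300, m = 500, s2a = 0.3, s2e = 0.7, seed = 42) {
  hw <- hweGenotypes(n, m, seed = seed)
  set.seed(seed + 1)
  cc <- 2 * sum(hw$p * (1 - hw$p))
  Z <- sweep(hw$geno, 2, 2 * hw$p, "-")
  uTrue <- rnorm(m, 0, sqrt(s2a / cc))
  y <- 1.5 + as.numeric(Z %*% uTrue) + rnorm(n, 0, sqrt(s2e))
  ped <- Pedigree(data.frame(animal = rownames(hw$geno), sire = NA,
                             dam = NA, generation = "G1"))
  phen <- data.frame(animal = rownames(hw$geno), sex = "X", cg = "c1",
                     y = y, stringsAsFactors = FALSE)
  list(geno = hw$geno, p = hw$p, Z = Z, cc = cc, y = y, ped = ped,
       phen = phen, s2a = s2a, s2e = s2e, uTrue = uTrue)
}

# single-trait ssGWAS over generation-subset scenarios; returns one
# WindowSet per scenario (windows on the scenario's own QC'd map; first/last
# SNP ids allow remapping to the full map)
runScenarioWindows <- function(out, cfg, scenarios, nIter = 3,
                               windowSize = 20) {
  ped <- out$pedigree
  gidsAll <- assignGenotyped(ped, out$phenotypes, cfg)
  Ainv <- buildAInverse(ped)
  spec <- modelSpec("bw", cfg@geneticCovariance, cfg@residualCovariance)
  ws <- lapply(scenarios, function(sp) {
    sub <- subsetScenario(out$phenotypes, gidsAll, sp, ped)
    g <- applyQC(out$geno[, sub$genotypedIds])$geno
    gids <- animalIds(g)
    p <- alleleFrequencies(g)
    G <- buildG(g, p = p)
    A22 <- extractA22(Ainv, gids)
    Gs <- tuneAndBlendG(G, A22)$G
    Hinv <- buildHInverse(Ainv, A22, Gs, gids)
    fit <- fitSSGBLUP(spec, sub$phen, ped, Hinv, tol = 1e-10)
    Zg <- sweep(genoMatrix(g), 2, 2 * p, "-")
    eff <- iterateWeights(Zg, fit$gebv[gids, "bw"], p, nIter = nIter,
                          A22 = A22, map = markerMap(g))
    v <- snpEffects(eff)
    windowVariances(v$variance, markerMap(g), n = windowSize)
  })
  names(ws) <- vapply(scenarios, `[[`, character(1), "name")
  ws
}

# percent of variance and top-k membership of the window containing a QTL
# marker, expressed on the reference map
qtlWindowStats <- function(ws, qtlSnp, refMap, k = 10) {
  d <- windowTable(ws)
  gi <- match(d$firstSnp, refMap$snp)
  ge <- match(d$lastSnp, refMap$snp)
  qi <- match(qtlSnp, refMap$snp)
  w <- which(gi <= qi & ge >= qi)
  if (!length(w)) return(c(pct = 0, top = 0))
  c(pct = d$pct[w[1]],
    top = as.numeric(rank(-d$variance, ties.method = "first")[w[1]] <= k))
}
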