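# Simulator: determinism, Mendelian transmission, selection response and
# recording structure.

smallConfig <- function(seed = 1, ...) {
  simConfig(offspringPerGeneration = 100, foundersPerSex = 25,
            nChromosomes = 2, snpsPerChromosome = 25,
            genotypingCountsPerGeneration = rep(20, 5), seed = seed, ...)
}

test_that("same config and seed reproduce the population exactly", {
  a <- simulatePopulation(smallConfig(seed = 11))
  b <- simulatePopulation(smallConfig(seed = 11))
  expect_identical(genoMatrix(a$geno), genoMatrix(b$geno))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$trueBreedingValues, b$truth$trueBreedingValues)
  c <- simulatePopulation(smallConfig(seed = 12))
  expect_false(identical(genoMatrix(a$geno), genoMatrix(c$geno)))
})

test_that("non-founder genotypes are Mendelian-consistent with parents", {
  out <- simulatePopulation(smallConfig(seed = 2))
  ped <- out$pedigree
  g <- genoMatrix(out$geno)
  offspring <- which(ped@sire > 0 & ped@dam > 0)
  set.seed(3)
  trios <- sample(offspring, 100)
  # gamete allele sets per gene content: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(x) as.integer(x == 2)       # smallest transmissible allele
  hi <- function(x) as.integer(x >= 1)       # largest transmissible allele
  for (i in trios) {
    cs <- g[ped@sire[i], ]; cd <- g[ped@dam[i], ]; cc <- g[i, ]
    expect_true(all(cc >= lo(cs) + lo(cd) & cc <= hi(cs) + hi(cd)))
  }
})

test_that("without selection mean breeding value does not drift", {
  drift <- sapply(1:20, function(s) {
    cfg <- simConfig(offspringPerGeneration = 100, foundersPerSex = 40,
                     nChromosomes = 1, snpsPerChromosome = 20, nQtl = 0,
                     selectionProportion = 1,
                     genotypingCountsPerGeneration = rep(0, 5), seed = 100 + s)
    out <- simulatePopulation(cfg)
    tbv <- out$truth$trueBreedingValues[, 1]
    gen <- out$pedigree@generation
    mean(tbv[gen == "G5"]) - mean(tbv[gen == "G1"])
  })
  se <- sd(drift) / sqrt(length(drift))
  expect_lt(abs(mean(drift)), 3 * se + 1e-12)
})

test_that("directional selection raises the favorable QTL allele frequency", {
  dfreq <- sapply(1:20, function(s) {
    cfg <- simConfig(offspringPerGeneration = 200, foundersPerSex = 40,
                     nChromosomes = 1, snpsPerChromosome = 40, nQtl = 1,
                     qtlVarianceFractions = 0.15, selectionProportion = 0.2,
                     nTraits = 1, maternalPeVariance = 0, sexEffects = 0,
                     genotypingCountsPerGeneration = rep(0, 5), seed = 200 + s)
    out <- simulatePopulation(cfg)
    qi <- out$truth$qtlPositions
    sgn <- sign(out$truth$qtlEffects[1, 1])  # frequency of the favorable allele
    fr <- out$truth$realizedAlleleFrequencies[qi, c("G1", "G5")]
    sgn * (fr["G5"] - fr["G1"])
  })
  expect_gt(mean(dfreq), 0)
  # and selection produces positive genetic gain
  cfg <- smallConfig(seed = 5)
  out <- simulatePopulation(cfg)
  tbv <- out$truth$trueBreedingValues[, 1]
  gen <- out$pedigree@generation
  expect_gt(mean(tbv[gen == "G5"]), mean(tbv[gen == "G1"]))
})

test_that("offspring-midparent regression recovers the configured h2", {
  h2 <- 0.25
  slopes <- sapply(1:3, function(s) {
    cfg <- simConfig(nTraits = 1, nQtl = 0, offspringPerGeneration = 2000,
                     foundersPerSex = 300, nChromosomes = 1,
                     snpsPerChromosome = 10, nGenerations = 2,
                     maternalPeVariance = 0, cgSd = 0, cgPerGeneration = 1,
                     sexEffects = 0, selectionProportion = 1,
                     genotypingCountsPerGeneration = rep(0, 2),
                     seed = 300 + s)
    out <- simulatePopulation(cfg)
    phen <- out$phenotypes
    ped <- out$pedigree
    g2 <- phen[phen$generation == "G2", ]
    idx <- match(g2$animal, ped@id)
    y1 <- setNames(phen$bw, phen$animal)
    mid <- (y1[ped@id[ped@sire[idx]]] + y1[ped@id[ped@dam[idx]]]) / 2
    keep <- !is.na(mid)
    unname(coef(lm(g2$bw[keep] ~ mid[keep]))[2])
  })
  expect_lt(abs(mean(slopes) - h2), 0.2 * h2)
})

test_that("founder-cohort breeding value variance matches the configuration", {
  cfg <- simConfig(offspringPerGeneration = 1500, foundersPerSex = 250,
                   nGenerations = 1, nChromosomes = 2, snpsPerChromosome = 40,
                   selectionProportion = 1,
                   genotypingCountsPerGeneration = 100, seed = 7)
  out <- simulatePopulation(cfg)
  gen <- out$pedigree@generation
  tbv <- out$truth$trueBreedingValues[gen == "G1", ]
  target <- diag(cfg@geneticCovariance)
  realized <- apply(tbv, 2, var)
  expect_true(all(abs(realized - target) < 0.25 * target))
})

test_that("genotyped-set assignment honours counts, ranking and edge cases", {
  cfg <- smallConfig(seed = 4)
  out <- simulatePopulation(cfg)
  ids <- assignGenotyped(out$pedigree, out$phenotypes, cfg)
  expect_length(ids, sum(cfg@genotypingCountsPerGeneration))
  expect_false(anyDuplicated(ids) > 0)
  # selective generations take the top-ranked animals on the selection trait
  phen <- out$phenotypes
  g1 <- phen[phen$generation == "G1", ]
  sel <- ids[ids %in% g1$animal]
  expect_gte(min(g1$bw[match(sel, g1$animal)]),
             sort(g1$bw, decreasing = TRUE)[length(sel)] - 1e-12)
  # zero count excludes the generation entirely
  cfg0 <- smallConfig(seed = 4)
  cfg0@genotypingCountsPerGeneration[3] <- 0L
  ids0 <- assignGenotyped(out$pedigree, out$phenotypes, cfg0)
  g3 <- phen$animal[phen$generation == "G3"]
  expect_length(intersect(ids0, g3), 0)
  # count = cohort size returns the whole cohort, selective or random alike
  cfgAll <- smallConfig(seed = 4)
  cfgAll@genotypingCountsPerGeneration[1] <- cfg@offspringPerGeneration
  idsAll <- assignGenotyped(out$pedigree, out$phenotypes, cfgAll)
  g1all <- phen$animal[phen$generation == "G1"]
  expect_setequal(intersect(idsAll, g1all), g1all)
})

test_that("phenotype summaries exclude missing records and flag empty traits", {
  d <- data.frame(animal = letters[1:4], x = c(1, 1, 1, 2),
                  y = c(2, NA, 4, NA), z = rep(NA_real_, 4))
  s <- summarizeSimulation(d, traits = c("x", "y", "z"))
  expect_equal(s$n, c(4L, 2L, 0L))
  expect_equal(s$mean[1], 1.25)
  expect_equal(s$mean[2], 3)
  expect_true(is.na(s$mean[3]))
  expect_false(s$defined[3])
  expect_error(summarizeSimulation(d[0, ]), "empty")
})

test_that("trait recording structure matches the configured world", {
  cfg <- simConfig(offspringPerGeneration = 2000, foundersPerSex = 100,
                   nGenerations = 2, nChromosomes = 1, snpsPerChromosome = 20,
                   selectionProportion = 0.5,
                   genotypingCountsPerGeneration = rep(10, 2), seed = 9)
  out <- simulatePopulation(cfg)
  s <- summarizeSimulation(out$phenotypes)
  # trait 2 recorded on ~ the configured fraction of animals
  frac <- s$n[s$trait == "bm"] / s$n[s$trait == "bw"]
  expect_lt(abs(frac - cfg@trait2RecordingFraction), 0.03)
  # quasi-categorical trait: values in {1,2}, mean near the threshold design
  leg <- out$phenotypes$leg
  expect_true(all(leg %in% c(1, 2)))
  expect_lt(abs(mean(leg) - 1.17), 0.08)
  # selected parent shortage is rejected
  tiny <- simConfig(offspringPerGeneration = 12, foundersPerSex = 6,
                    selectionProportion = 0.1, nChromosomes = 1,
                    snpsPerChromosome = 10,
                    genotypingCountsPerGeneration = rep(0, 5), seed = 1)
  expect_error(simulatePopulation(tiny), "selected parent count")
})
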