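# Scenario subsetting, window matching across tilings, persistence reports
# and the chromosome-segment formula.

mkWindowSet <- function(df, total = sum(df$variance), n = 20L) {
  df$pct <- df$variance / total * 100
  df$nSnps <- df$end - df$start + 1L
  if (is.null(df$firstSnp)) df$firstSnp <- paste0("s", df$start)
  if (is.null(df$lastSnp)) df$lastSnp <- paste0("s", df$end)
  new("WindowSet", data = df, totalVariance = total, windowSize = n)
}

test_that("scenario subsetting filters by generation and errors when empty", {
  phen <- data.frame(animal = paste0("a", 1:10),
                     generation = rep(paste0("G", 1:5), each = 2),
                     bw = rnorm(10))
  geno <- paste0("a", c(1, 3, 5, 7, 9))
  scen <- canonicalScenarios()
  expect_equal(names(scen), c("ALL", "G1-G3", "G2-G4", "G3-G5"))
  allS <- subsetScenario(phen, geno, scen$ALL)
  expect_equal(allS$phen, phen)          # identity on the complete scenario
  expect_equal(allS$genotypedIds, geno)
  g13 <- subsetScenario(phen, geno, scen$`G1-G3`)
  expect_equal(g13$phen$generation, rep(c("G1", "G2", "G3"), each = 2))
  expect_equal(g13$genotypedIds, paste0("a", c(1, 3, 5)))
  none <- scenarioSpec("late", paste0("G", 4:5), "G9")
  expect_error(subsetScenario(phen, geno, none), "no genotyped animals")
})

test_that("window matching follows the overlap rules", {
  a <- mkWindowSet(data.frame(chr = "1", start = 10L, end = 29L, variance = 5))
  b <- mkWindowSet(data.frame(chr = "1", start = 25L, end = 44L, variance = 4))
  expect_equal(nrow(windowMatching(a, b, "any")), 1)       # 5-SNP overlap
  expect_equal(windowMatching(a, b, "any")$overlap, 5L)
  expect_equal(nrow(windowMatching(a, b, "reciprocal50")), 0)
  # identical tilings match perfectly
  t1 <- mkWindowSet(data.frame(chr = c("1", "1"), start = c(1L, 11L),
                               end = c(10L, 20L), variance = c(2, 8)))
  m <- windowMatching(t1, t1)
  expect_equal(m$rowA, m$rowB)
  # disjoint ranges never match
  c1 <- mkWindowSet(data.frame(chr = "1", start = 1L, end = 5L, variance = 1))
  c2 <- mkWindowSet(data.frame(chr = "1", start = 6L, end = 9L, variance = 1))
  expect_equal(nrow(windowMatching(c1, c2)), 0)
  # different chromosomes never match
  c3 <- mkWindowSet(data.frame(chr = "2", start = 1L, end = 5L, variance = 1))
  expect_equal(nrow(windowMatching(c1, c3)), 0)
})

test_that("identical scenarios give full persistence; divergent pct is flagged", {
  ws <- mkWindowSet(data.frame(chr = rep("1", 4), start = c(1L, 21L, 41L, 61L),
                               end = c(20L, 40L, 60L, 80L),
                               variance = c(40, 30, 20, 10)))
  rep4 <- persistenceReport(list(s1 = ws, s2 = ws, s3 = ws, s4 = ws), k = 2)
  t <- reportTable(rep4)
  expect_equal(nrow(t), 2)
  expect_true(all(t$persistence == 4))
  expect_false(any(t$lowElsewhere))
  # a window top in scenario A but nearly zero-variance in B gets flagged
  wsA <- mkWindowSet(data.frame(chr = rep("1", 2), start = c(1L, 21L),
                                end = c(20L, 40L), variance = c(99, 1)),
                     total = 100)
  wsB <- mkWindowSet(data.frame(chr = rep("1", 2), start = c(1L, 21L),
                                end = c(20L, 40L), variance = c(0.01, 99.99)),
                     total = 100)
  r <- persistenceReport(list(A = wsA, B = wsB), k = 1)
  t2 <- reportTable(r)
  first <- t2[t2$start == 1, ]
  expect_equal(first$persistence, 1)
  expect_true(first$lowElsewhere)          # 0.01% < 0.1% in scenario B
  expect_error(persistenceReport(list(wsA)), "length")
})

test_that("chromosome segment count follows 2NeL/ln(4NeL)", {
  expect_equal(qSegments(50, 39), 435)
  # ln = 1 case: 4 Ne L = e  ->  q = 2 Ne L
  NeL <- exp(1) / 4
  expect_equal(qSegments(1, NeL, round = FALSE), 2 * NeL)
  # monotone increasing in Ne at fixed L
  q <- sapply(10:1000, qSegments, L = 39, round = FALSE)
  expect_true(all(diff(q) > 0))
  expect_error(qSegments(-1, 10), "Ne > 0")
})

test_that("a stable simulated QTL persists across all scenario top-10s", {
  hits <- sapply(1:3, function(seed) {
    cfg <- simConfig(nGenerations = 5, nTraits = 1, nQtl = 1,
                     qtlVarianceFractions = 0.2, qtlFounderFreq = 0.5,
                     geneticCovariance = matrix(0.3),
                     residualCovariance = matrix(0.7),
                     offspringPerGeneration = 400, foundersPerSex = 60,
                     nChromosomes = 3, snpsPerChromosome = 200,
                     maternalPeVariance = 0, cgSd = 0, cgPerGeneration = 1,
                     sexEffects = 0, selectionProportion = 1,
                     genotypingCountsPerGeneration = rep(120, 5),
                     selectiveGenotypingGenerations = integer(0),
                     seed = 500 + seed)
    out <- simulatePopulation(cfg)
    ws <- runScenarioWindows(out, cfg, canonicalScenarios())
    refMap <- markerMap(out$geno)
    qtlSnp <- refMap$snp[out$truth$qtlPositions]
    st <- sapply(ws, qtlWindowStats, qtlSnp, refMap)
    all(st["top", ] == 1)
  })
  expect_gte(sum(hits), 2)   # full 10-seed version runs in the acceptance suite
})
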