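# File formats round-trip and the QC filter chain.

toyGeno <- function() {
  # 25 animals: A monomorphic; B MAF 0.04 (2 copies / 50); C call rate 0.88;
  # D MAF 0.3 with full calls
  g <- cbind(
    A = rep(2, 25),
    B = c(1, 1, rep(0, 23)),
    C = c(NA, NA, NA, rep(1, 22)),
    D = c(rep(1, 15), rep(0, 10)))
  rownames(g) <- sprintf("an%02d", 1:25)
  GenotypeData(g, data.frame(snp = colnames(g), chr = 1, pos = 1:4 * 10))
}

test_that("QC removes SNPs by the first triggering rule and animals after", {
  g <- toyGeno()
  res <- applyQC(g, qcThresholds())   # defaults: MAF 0.05, call rate 0.9
  d <- res$report$snpsRemoved
  expect_setequal(d$snp, c("A", "B", "C"))
  expect_equal(d$reason[d$snp == "A"], "monomorphic")
  expect_equal(d$reason[d$snp == "C"], "snp_call_rate")
  expect_equal(d$reason[d$snp == "B"], "maf")
  expect_equal(colnames(genoMatrix(res$geno)), "D")
  expect_equal(nrow(genoMatrix(res$geno)), 25)
  # MAF exactly at the threshold survives (strict <)
  res2 <- applyQC(g, qcThresholds(minMaf = 0.04))
  expect_true("B" %in% colnames(genoMatrix(res2$geno)))
})

test_that("animal call-rate filter acts on surviving SNPs", {
  g <- cbind(a = c(0, 1, 2, 1), b = c(NA, 1, 0, 2), c = rep(1, 4))
  g[1, "c"] <- NA     # animal 1 misses 2 of 3 SNPs
  rownames(g) <- paste0("x", 1:4)
  gd <- GenotypeData(g, data.frame(snp = colnames(g), chr = 1, pos = 1:3))
  res <- applyQC(gd, qcThresholds(minMaf = 0, minSnpCallRate = 0,
                                  minAnimalCallRate = 0.9,
                                  dropMonomorphic = FALSE))
  expect_equal(res$report$animalsRemoved$animal, "x1")
  expect_equal(rownames(genoMatrix(res$geno)), paste0("x", 2:4))
})

test_that("null thresholds leave the data unchanged and QC is idempotent", {
  g <- toyGeno()
  t0 <- qcThresholds(minMaf = 0, minSnpCallRate = 0, minAnimalCallRate = 0,
                     dropMonomorphic = FALSE)
  res <- applyQC(g, t0)
  expect_equal(genoMatrix(res$geno), genoMatrix(g))
  t1 <- qcThresholds(minMaf = 0.06)
  once <- applyQC(g, t1)
  twice <- applyQC(once$geno, t1)
  expect_equal(genoMatrix(twice$geno), genoMatrix(once$geno))
  expect_equal(nrow(twice$report$snpsRemoved), 0)
  # filter-count conservation: every input SNP survives or is counted once
  expect_equal(once$report$counts[["snpsIn"]],
               once$report$counts[["snpsOut"]] +
                 nrow(once$report$snpsRemoved))
  # all-removed is an explicit error
  expect_error(applyQC(g, qcThresholds(minMaf = 0.51)), "every SNP")
})

test_that("allele frequencies use non-missing calls", {
  g <- cbind(s1 = c(0, 1, 2), s2 = c(2, 2, 2), s3 = c(0, NA, 1))
  rownames(g) <- paste0("a", 1:3)
  gd <- GenotypeData(g, data.frame(snp = colnames(g), chr = 1, pos = 1:3))
  p <- alleleFrequencies(gd)
  expect_equal(unname(p), c(0.5, 1, 0.25))
  g[, 3] <- NA
  expect_error(alleleFrequencies(g), "no non-missing call")
})

test_that("PED/MAP and CSV round-trips are identities", {
  set.seed(10)
  hw <- hweGenotypes(6, 8, seed = 10)
  geno <- hw$geno
  geno[2, 3] <- NA
  map <- data.frame(snp = colnames(geno), chr = rep(1:2, each = 4),
                    pos = rep(1:4 * 100, 2))
  gd <- GenotypeData(geno, map)
  td <- withr::local_tempdir()
  writeGenotypesPed(gd, file.path(td, "g.ped"), file.path(td, "g.map"))
  back <- readGenotypesPed(file.path(td, "g.ped"), file.path(td, "g.map"))
  expect_equal(genoMatrix(back), genoMatrix(gd))
  expect_equal(markerMap(back), markerMap(gd))
  writeGenotypesCsv(gd, file.path(td, "g.csv"), file.path(td, "m.csv"))
  back2 <- readGenotypesCsv(file.path(td, "g.csv"), file.path(td, "m.csv"))
  expect_equal(genoMatrix(back2), genoMatrix(gd))
  # malformed PED row reported with its line number
  writeLines(c("F a1 0 0 0 -9 1 2", "F a2 0 0 0 -9 1"),
             file.path(td, "bad.ped"))
  writeLines("1 s1 0 100", file.path(td, "bad.map"))
  expect_error(readGenotypesPed(file.path(td, "bad.ped"),
                                file.path(td, "bad.map")), "lines 2")
})

test_that("pedigree and phenotype CSVs round-trip; disorder is repaired", {
  td <- withr::local_tempdir()
  # sire listed after its offspring: reordered, not an error
  df <- data.frame(animal = c("kid", "pa", "ma"),
                   sire = c("pa", NA, NA), dam = c("ma", NA, NA),
                   generation = c("G1", "G0", "G0"))
  ped <- Pedigree(df)
  expect_equal(ped@id, c("pa", "ma", "kid"))
  writePedigree(ped, file.path(td, "ped.csv"))
  back <- readPedigree(file.path(td, "ped.csv"))
  expect_equal(pedigreeTable(back), pedigreeTable(ped))
  expect_error(Pedigree(data.frame(animal = c("a", "a"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(Pedigree(data.frame(animal = "a", sire = "ghost", dam = NA)),
               "not in pedigree")
  # a cycle is an error, not an infinite loop
  expect_error(Pedigree(data.frame(animal = c("a", "b"), sire = c("b", "a"),
                                   dam = NA)), "cycle")
  phen <- data.frame(animal = c("x", "y"), sex = c("M", "F"),
                     cg = "c1", bw = c(1.2, NA))
  writePhenotypes(phen, file.path(td, "ph.csv"))
  expect_equal(readPhenotypes(file.path(td, "ph.csv"))$bw, c(1.2, NA))
  writeLines(c("animal,bw", "x,1", "x,2"), file.path(td, "dup.csv"))
  expect_error(readPhenotypes(file.path(td, "dup.csv")), "duplicate")
})
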