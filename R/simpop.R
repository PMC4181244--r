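# Simulation of a multi-generation line under truncation selection:
# discrete generations, Mendelian gamete transmission with Haldane
# recombination, a mixed architecture of moderate QTL placed on markers plus
# an infinitesimal polygenic background, correlated traits with sex /
# contemporary-group / maternal permanent-environment structure, selective
# genotyping in early generations.

.traitNames <- function(nTraits) {
  if (nTraits <= 3) c("bw", "bm", "leg")[seq_len(nTraits)]
  else paste0("trait", seq_len(nTraits))
}

#' Configure the simulated population
#'
#' All defaults describe a desk-scale analogue of a broiler sire line under
#' truncation selection: five discrete generations, three correlated traits
#' (a fully recorded growth trait, a carcass trait recorded on about a quarter
#' of animals, and a quasi-categorical leg score obtained by thresholding a
#' Gaussian liability and analyzed linearly), maternal permanent-environment
#' effects, and genotyping that is phenotype-ranked in the first two
#' generations and random afterwards.
#'
#' Latent phenotypic variance is 1 per trait; heritabilities default to
#' 0.25 / 0.30 / 0.10 with genetic correlations 0.5 / 0.2 / 0.1.  Each QTL is
#' placed on a marker and assigned a fraction of the additive variance of the
#' selection trait; the remainder is polygenic.
#'
#' @param nGenerations number of phenotyped cohorts (default 5).
#' @param foundersPerSex unrelated base animals per sex (generation "G0").
#' @param offspringPerGeneration cohort size of each phenotyped generation.
#' @param nChromosomes,snpsPerChromosome,chromosomeLengthMorgans marker panel:
#'   evenly spaced SNPs, genetic length per chromosome in Morgans (crossover
#'   count is Poisson with this mean).
#' @param nQtl,qtlVarianceFractions number of marker-QTL and the fraction of
#'   the selection trait's additive variance assigned to each.
#' @param qtlFounderFreq optional fixed founder allele frequency for the QTL
#'   markers (length 1 or nQtl); default draws from U(0.25, 0.75).
#' @param nTraits number of traits (default 3).
#' @param geneticCovariance,residualCovariance trait x trait covariance of
#'   additive values and residuals.
#' @param maternalPeVariance per-trait variance of the dam permanent
#'   environment effect.
#' @param sexEffects per-trait fixed effect added for males.
#' @param cgPerGeneration,cgSd number of contemporary (hatch) groups per
#'   generation and the SD of their per-trait effects.
#' @param selectionProportion fraction of each sex kept as parents of the next
#'   generation (truncation on the selection trait's phenotype).
#' @param selectionTraitIndex which trait drives selection.
#' @param genotypingCountsPerGeneration animals genotyped per generation.
#' @param selectiveGenotypingGenerations generations (1-based) where the
#'   genotyped animals are the top-ranked on the selection trait rather than a
#'   random sample.
#' @param trait2RecordingFraction fraction of animals with a trait-2 record.
#' @param trait3Threshold liability cut point for the quasi-categorical trait
#'   (recorded as 1 below, 2 above).
#' @param seed RNG seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nGenerations = 5,
                      foundersPerSex = 40,
                      offspringPerGeneration = 300,
                      nChromosomes = 3,
                      snpsPerChromosome = 100,
                      chromosomeLengthMorgans = 1,
                      nQtl = 5,
                      qtlVarianceFractions = rep(0.05, nQtl),
                      qtlFounderFreq = numeric(0),
                      nTraits = 3,
                      geneticCovariance = NULL,
                      residualCovariance = NULL,
                      maternalPeVariance = rep(0.05, nTraits),
                      sexEffects = c(0.5, 0.3, 0)[seq_len(nTraits)],
                      cgPerGeneration = 4,
                      cgSd = rep(sqrt(0.05), nTraits),
                      selectionProportion = 0.2,
                      selectionTraitIndex = 1,
                      genotypingCountsPerGeneration = rep(60, nGenerations),
                      selectiveGenotypingGenerations = c(1, 2),
                      trait2RecordingFraction = 0.256,
                      trait3Threshold = qnorm(0.83),
                      seed = 1) {
  h2 <- c(0.25, 0.30, 0.10, rep(0.25, max(0, nTraits - 3)))[seq_len(nTraits)]
  if (is.null(geneticCovariance)) {
    rg <- diag(nTraits)
    if (nTraits >= 2) rg[1, 2] <- rg[2, 1] <- 0.5
    if (nTraits >= 3) { rg[1, 3] <- rg[3, 1] <- 0.2; rg[2, 3] <- rg[3, 2] <- 0.1 }
    geneticCovariance <- rg * tcrossprod(sqrt(h2))
  }
  if (is.null(residualCovariance)) {
    se <- pmax(1 - diag(geneticCovariance) - maternalPeVariance, 0.1)
    re <- diag(nTraits)
    if (nTraits >= 2) re[1, 2] <- re[2, 1] <- 0.2
    if (nTraits >= 3) { re[1, 3] <- re[3, 1] <- 0.05; re[2, 3] <- re[3, 2] <- 0.05 }
    residualCovariance <- re * tcrossprod(sqrt(se))
  }
  if (length(sexEffects) < nTraits)
    sexEffects <- c(sexEffects, rep(0, nTraits - length(sexEffects)))
  new("SimConfig",
      nGenerations = as.integer(nGenerations),
      foundersPerSex = as.integer(foundersPerSex),
      offspringPerGeneration = as.integer(offspringPerGeneration),
      nChromosomes = as.integer(nChromosomes),
      snpsPerChromosome = as.integer(snpsPerChromosome),
      chromosomeLengthMorgans = as.numeric(chromosomeLengthMorgans),
      nQtl = as.integer(nQtl),
      qtlVarianceFractions = as.numeric(qtlVarianceFractions),
      qtlFounderFreq = as.numeric(qtlFounderFreq),
      nTraits = as.integer(nTraits),
      geneticCovariance = geneticCovariance,
      residualCovariance = residualCovariance,
      maternalPeVariance = as.numeric(maternalPeVariance),
      sexEffects = as.numeric(sexEffects),
      cgPerGeneration = as.integer(cgPerGeneration),
      cgSd = as.numeric(cgSd),
      selectionProportion = as.numeric(selectionProportion),
      selectionTraitIndex = as.integer(selectionTraitIndex),
      genotypingCountsPerGeneration = as.integer(genotypingCountsPerGeneration),
      selectiveGenotypingGenerations = as.integer(selectiveGenotypingGenerations),
      trait2RecordingFraction = as.numeric(trait2RecordingFraction),
      trait3Threshold = as.numeric(trait3Threshold),
      seed = as.integer(seed))
}

# One gamete: per chromosome, Poisson(L) crossovers uniform on the genetic
# map, random start haplotype, alternate at each crossover (Haldane model).
.gamete <- function(h1, h2, chrIdx, gpos, chrLen) {
  out <- integer(length(h1))
  for (c in seq_along(chrIdx)) {
    ii <- chrIdx[[c]]
    nx <- rpois(1L, chrLen[c])
    hap <- rbinom(1L, 1L, 0.5)
    if (nx == 0L) {
      out[ii] <- if (hap == 0L) h1[ii] else h2[ii]
    } else {
      xo <- sort(runif(nx, 0, chrLen[c]))
      sel <- (hap + findInterval(gpos[ii], xo)) %% 2L
      out[ii] <- ifelse(sel == 0L, h1[ii], h2[ii])
    }
  }
  out
}

#' Simulate a selected multi-generation population
#'
#' Produces an unrelated founder layer ("G0", random-mated to create the first
#' cohort) followed by `nGenerations` phenotyped cohorts in which the parents
#' of each cohort are the top `selectionProportion` of the previous cohort per
#' sex, ranked on the selection trait's recorded phenotype.  Phenotype =
#' sex effect + contemporary-group effect + additive genetic value +
#' maternal permanent environment of the dam + residual.  Trait 2 is recorded
#' on a random fraction of animals; trait 3 is recorded as 1/2 by thresholding
#' its Gaussian liability.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A list with elements `pedigree` ([Pedigree-class]), `geno`
#'   ([GenotypeData-class] for all simulated animals, founders included),
#'   `phenotypes` (data.frame over the phenotyped cohorts), and `truth`, a
#'   list with `trueBreedingValues` (animals x traits), `qtlPositions` (map
#'   indices), `qtlEffects` (QTL x traits allele substitution effects),
#'   `realizedAlleleFrequencies` (SNP x generation matrix) and `polygenic`
#'   (the polygenic component of the breeding values).
#' @export
simulatePopulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nGen <- config@nGenerations
  N <- config@offspringPerGeneration
  nT <- config@nTraits
  tn <- .traitNames(nT)
  selT <- config@selectionTraitIndex
  nChr <- config@nChromosomes
  mPerChr <- config@snpsPerChromosome
  m <- nChr * mPerChr
  chrLen <- rep(config@chromosomeLengthMorgans, length.out = nChr)

  # marker map: evenly spaced, 1 cM ~ 1 Mb on the physical scale
  chr <- rep(seq_len(nChr), each = mPerChr)
  gposWithin <- unlist(lapply(seq_len(nChr), function(c)
    (seq_len(mPerChr) - 0.5) / mPerChr * chrLen[c]))
  map <- data.frame(snp = sprintf("snp%04d", seq_len(m)), chr = chr,
                    pos = round(gposWithin * 1e8), stringsAsFactors = FALSE)
  chrIdx <- split(seq_len(m), chr)

  # founder allele frequencies; QTL markers kept at intermediate frequency
  pf <- runif(m, 0.1, 0.9)
  qtlIdx <- integer(0)
  alpha <- matrix(0, 0, nT)
  G0 <- config@geneticCovariance
  G0poly <- G0
  if (config@nQtl > 0) {
    qtlIdx <- sort(sample.int(m, config@nQtl))
    pf[qtlIdx] <- if (length(config@qtlFounderFreq))
      rep(config@qtlFounderFreq, length.out = config@nQtl)
    else runif(config@nQtl, 0.25, 0.75)
    # fully pleiotropic QTL along the genetic regression on the selection
    # trait; remainder of the additive covariance is polygenic
    v <- G0[, selT] / G0[selT, selT]
    s <- sqrt(config@qtlVarianceFractions * G0[selT, selT] /
              (2 * pf[qtlIdx] * (1 - pf[qtlIdx])))
    alpha <- s %o% v
    G0poly <- G0 - sum(config@qtlVarianceFractions) * G0[selT, selT] *
      tcrossprod(v)
  }

  nF <- 2L * config@foundersPerSex
  nTotal <- nF + nGen * N
  ids <- sprintf("an%06d", seq_len(nTotal))
  hapA <- matrix(0L, nTotal, m)
  hapB <- matrix(0L, nTotal, m)
  sire <- integer(nTotal); dam <- integer(nTotal)
  genLab <- character(nTotal)
  sex <- character(nTotal)
  poly <- matrix(0, nTotal, nT)
  pe <- .rmvn(nTotal, diag(config@maternalPeVariance, nT))
  resid <- matrix(NA_real_, nTotal, nT)
  cgLab <- character(nTotal)

  # founders
  fi <- seq_len(nF)
  hapA[fi, ] <- matrix(rbinom(nF * m, 1L, rep(pf, each = nF)), nF, m)
  hapB[fi, ] <- matrix(rbinom(nF * m, 1L, rep(pf, each = nF)), nF, m)
  genLab[fi] <- "G0"
  sex[fi] <- rep(c("M", "F"), each = config@foundersPerSex)
  poly[fi, ] <- .rmvn(nF, G0poly)
  cgLab[fi] <- NA_character_

  tbvOf <- function(rows) {
    tb <- poly[rows, , drop = FALSE]
    if (length(qtlIdx))
      tb <- tb + (hapA[rows, qtlIdx, drop = FALSE] +
                  hapB[rows, qtlIdx, drop = FALSE]) %*% alpha
    tb
  }

  phenRows <- vector("list", nGen)
  yAll <- matrix(NA_real_, nTotal, nT)
  sires <- which(sex == "M" & genLab == "G0")
  dams  <- which(sex == "F" & genLab == "G0")
  for (g in seq_len(nGen)) {
    rows <- nF + (g - 1L) * N + seq_len(N)
    sire[rows] <- sample(sires, N, replace = TRUE)
    dam[rows]  <- sample(dams, N, replace = TRUE)
    for (i in rows) {
      hapA[i, ] <- .gamete(hapA[sire[i], ], hapB[sire[i], ], chrIdx,
                           gposWithin, chrLen)
      hapB[i, ] <- .gamete(hapA[dam[i], ], hapB[dam[i], ], chrIdx,
                           gposWithin, chrLen)
    }
    genLab[rows] <- paste0("G", g)
    sex[rows] <- ifelse(rbinom(N, 1L, 0.5) == 1L, "M", "F")
    poly[rows, ] <- 0.5 * (poly[sire[rows], , drop = FALSE] +
                           poly[dam[rows], , drop = FALSE]) +
      .rmvn(N, 0.5 * G0poly)
    cg <- sample.int(config@cgPerGeneration, N, replace = TRUE)
    cgLab[rows] <- sprintf("G%d_cg%d", g, cg)
    cgEff <- matrix(rnorm(config@cgPerGeneration * nT, 0,
                          rep(config@cgSd, each = config@cgPerGeneration)),
                    config@cgPerGeneration, nT)
    resid[rows, ] <- .rmvn(N, config@residualCovariance)
    y <- tbvOf(rows) + resid[rows, , drop = FALSE] + cgEff[cg, , drop = FALSE] +
      (sex[rows] == "M") %o% config@sexEffects +
      pe[dam[rows], , drop = FALSE]
    # trait-2 selective recording, trait-3 thresholding (recorded 1/2)
    if (nT >= 2) {
      miss <- runif(N) > config@trait2RecordingFraction
      y[miss, 2] <- NA_real_
    }
    if (nT >= 3) y[, 3] <- 1 + (y[, 3] > config@trait3Threshold)
    yAll[rows, ] <- y
    phenRows[[g]] <- rows
    # parents of the next generation: within-sex truncation on the recorded
    # phenotype of the selection trait (random tie-break)
    if (g < nGen) {
      ySel <- y[, selT]
      for (sx in c("M", "F")) {
        cand <- rows[sex[rows] == sx]
        nSel <- floor(config@selectionProportion * length(cand))
        if (nSel < 2)
          stop("selected parent count < 2 for sex ", sx,
               " in generation G", g)
        ord <- order(-ySel[match(cand, rows)], runif(length(cand)))
        keep <- cand[ord[seq_len(nSel)]]
        if (sx == "M") sires <- keep else dams <- keep
      }
    }
  }

  genoAll <- hapA + hapB
  rownames(genoAll) <- ids
  geno <- GenotypeData(genoAll, map)

  ped <- new("Pedigree", id = ids, sire = as.integer(sire),
             dam = as.integer(dam), generation = genLab)
  validObject(ped)

  rowsPhen <- unlist(phenRows)
  phen <- data.frame(animal = ids[rowsPhen],
                     generation = genLab[rowsPhen],
                     sex = sex[rowsPhen],
                     cg = cgLab[rowsPhen],
                     dam = ids[dam[rowsPhen]],
                     stringsAsFactors = FALSE)
  for (t in seq_len(nT)) phen[[tn[t]]] <- yAll[rowsPhen, t]

  tbv <- tbvOf(seq_len(nTotal))
  rownames(tbv) <- ids
  colnames(tbv) <- tn
  genLevels <- c("G0", paste0("G", seq_len(nGen)))
  freqs <- sapply(genLevels, function(gl) {
    rows <- which(genLab == gl)
    colMeans(genoAll[rows, , drop = FALSE]) / 2
  })
  rownames(freqs) <- map$snp

  list(pedigree = ped,
       geno = geno,
       phenotypes = phen,
       truth = list(trueBreedingValues = tbv,
                    qtlPositions = qtlIdx,
                    qtlEffects = alpha,
                    founderFrequencies = pf,
                    realizedAlleleFrequencies = freqs,
                    polygenic = poly))
}

#' Select the genotyped animals
#'
#' In the generations listed in `selectiveGenotypingGenerations` the top-ranked
#' animals on the selection trait's phenotype are genotyped (emulating
#' genotyping by performance in early generations); elsewhere a seeded uniform
#' sample is taken.  Set sizes match `genotypingCountsPerGeneration`.
#'
#' @param pedigree a [Pedigree-class].
#' @param phenotypes phenotype data.frame with columns `animal`, `generation`
#'   and the trait columns.
#' @param config a [SimConfig-class] (supplies counts, the selective set and
#'   the selection trait).
#' @param seed seed for the random-sampling generations (default: the config
#'   seed, so the choice is reproducible).
#' @param traitColumn phenotype column used for ranking in selective
#'   generations.
#' @return Character vector of genotyped animal ids.
#' @export
assignGenotyped <- function(pedigree, phenotypes, config,
                            seed = config@seed,
                            traitColumn = .traitNames(config@nTraits)[
                              config@selectionTraitIndex]) {
  set.seed(.deriveSeed(seed, 97L))
  out <- character(0)
  for (g in seq_len(config@nGenerations)) {
    cnt <- config@genotypingCountsPerGeneration[g]
    if (cnt == 0L) next
    gl <- paste0("G", g)
    sub <- phenotypes[phenotypes$generation == gl, , drop = FALSE]
    if (cnt > nrow(sub))
      stop("genotyping count ", cnt, " exceeds cohort size ", nrow(sub),
           " in generation ", gl)
    if (g %in% config@selectiveGenotypingGenerations) {
      ord <- order(-sub[[traitColumn]], runif(nrow(sub)))
      out <- c(out, sub$animal[ord[seq_len(cnt)]])
    } else {
      out <- c(out, sample(sub$animal, cnt))
    }
  }
  out
}

#' Per-trait summary of a phenotype table
#'
#' Counts, means and SDs per trait, excluding missing records.  An all-missing
#' trait yields `n = 0` and `NA` mean/SD (flagged in the `defined` column).
#'
#' @param phenotypes phenotype data.frame.
#' @param traits trait column names; defaults to every column that is not
#'   animal/generation/sex/cg/dam metadata.
#' @return data.frame with columns `trait`, `n`, `mean`, `sd`, `defined`.
#' @export
summarizeSimulation <- function(phenotypes, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(colnames(phenotypes),
                      c("animal", "generation", "sex", "cg", "dam"))
  if (!nrow(phenotypes)) stop("empty phenotype table")
  out <- lapply(traits, function(tr) {
    v <- phenotypes[[tr]]
    v <- v[!is.na(v)]
    data.frame(trait = tr, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               defined = length(v) > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
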