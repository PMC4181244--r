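#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal Cholesky forceSymmetric bdiag
#'   solve crossprod t diag rowSums colSums
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats rnorm rbinom rpois runif sd var qnorm dnorm coef lm
#'   setNames aggregate
#' @importFrom utils read.table write.table count.fields head capture.output
NULL

# ---------------------------------------------------------------------------
# GenotypeData: gene-content matrix (0/1/2, NA = no call) plus marker map.
# Stored SNPs x animals in the SummarizedExperiment convention; user-facing
# accessors present the animals x SNPs orientation used in the linear algebra.
# ---------------------------------------------------------------------------

#' GenotypeData: gene content with a marker map
#'
#' Container for additive-coded genotypes (counts of the map-defined second
#' allele: 0, 1, 2, or `NA` for a missing call) together with the marker map
#' (chromosome, base-pair position).  Extends
#' [SummarizedExperiment::SummarizedExperiment] with SNPs as rows and animals
#' as columns; the map lives in `rowData`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character(0)
  if (!("geno" %in% assayNames(object)))
    msg <- c(msg, "assay 'geno' is required")
  rd <- rowData(object)
  if (!all(c("chr", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chr' and 'pos'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "animal ids (colnames) must be present and unique")
  if (length(msg) == 0 && nrow(object) > 1) {
    chr <- as.character(rd$chr)
    pos <- as.numeric(rd$pos)
    # chromosome blocks contiguous, positions non-decreasing within block
    blocks <- rle(chr)$values
    if (anyDuplicated(blocks))
      msg <- c(msg, "marker map must be sorted: chromosome blocks not contiguous")
    else if (any(unlist(tapply(pos, factor(chr, levels = unique(chr)), is.unsorted))))
      msg <- c(msg, "marker map must be sorted by position within chromosome")
  }
  if (length(msg) == 0) {
    g <- assay(object, "geno")
    bad <- !(is.na(g) | g == 0 | g == 1 | g == 2)
    if (any(bad)) msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param geno numeric matrix, animals x SNPs, values 0/1/2/`NA`; rownames are
#'   animal ids, colnames SNP ids (generated if absent).
#' @param map data.frame with columns `snp`, `chr`, `pos` (base pairs).  Rows
#'   are reordered to (chromosome, position) order and the genotype columns
#'   follow.
#' @return A [GenotypeData-class] object.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 1, 0), nrow = 3,
#'             dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
#' gd <- GenotypeData(g, data.frame(snp = c("s1", "s2"), chr = 1, pos = c(10, 20)))
#' nSnps(gd)
#' @export
GenotypeData <- function(geno, map) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("id", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- map$snp
  map <- as.data.frame(map)
  stopifnot(all(c("snp", "chr", "pos") %in% colnames(map)),
            nrow(map) == ncol(geno))
  if (!all(colnames(geno) == map$snp))
    geno <- geno[, match(map$snp, colnames(geno)), drop = FALSE]
  ord <- order(factor(map$chr, levels = unique(map$chr)), map$pos)
  # keep chromosomes in first-appearance order, positions ascending
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rd <- DataFrame(chr = map$chr, pos = map$pos, row.names = map$snp)
  se <- SummarizedExperiment(assays = list(geno = t(geno)), rowData = rd)
  new("GenotypeData", se)
}

# ---------------------------------------------------------------------------
# Pedigree: renumbered animal/sire/dam triplets with generation labels.
# ---------------------------------------------------------------------------

#' Pedigree: renumbered animal/sire/dam records
#'
#' Topologically ordered pedigree (parents always precede offspring).  Animals
#' are stored by positional index 1..n; `sire`/`dam` hold the parent's index
#' or 0 when unknown.  `id` keeps the original labels.
#'
#' @slot id character, original animal labels in renumbered order.
#' @slot sire,dam integer, parent positional index, 0 = unknown.
#' @slot generation character, cohort label per animal.
#' @export
setClass("Pedigree",
         representation(id = "character", sire = "integer",
                        dam = "integer", generation = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character(0)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@generation) != n)
    msg <- c(msg, "slot lengths differ")
  if (anyDuplicated(object@id)) msg <- c(msg, "duplicate animal ids")
  idx <- seq_len(n)
  if (n && (any(object@sire < 0) || any(object@dam < 0) ||
            any(object@sire >= idx) || any(object@dam >= idx)))
    msg <- c(msg, "parents must precede offspring (topological order violated)")
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree, renumbering and reordering as needed
#'
#' Accepts a data.frame with columns `animal`, `sire`, `dam` and optionally
#' `generation`.  Unknown parents are `NA`, `""` or `"0"`.  Rows are
#' topologically sorted (so a sire listed after its offspring is reordered,
#' not an error); a parent id absent from the animal column is an error.
#'
#' @param df pedigree data.frame.
#' @return A [Pedigree-class] object.
#' @export
Pedigree <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("animal", "sire", "dam") %in% colnames(df)))
  an <- as.character(df$animal)
  if (anyDuplicated(an))
    stop("duplicate animal ids in pedigree: ",
         paste(unique(an[duplicated(an)]), collapse = ", "))
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0" | x == "NA"] <- NA_character_
    x
  }
  si <- clean(df$sire); da <- clean(df$dam)
  unknownParents <- setdiff(c(si[!is.na(si)], da[!is.na(da)]), an)
  if (length(unknownParents))
    stop("parent ids not in pedigree: ",
         paste(head(unknownParents, 5), collapse = ", "))
  gen <- if ("generation" %in% colnames(df)) as.character(df$generation)
         else rep(NA_character_, nrow(df))
  # Kahn-style topological sort, stable in input order
  n <- length(an)
  pos <- seq_len(n)
  sidx <- match(si, an); didx <- match(da, an)  # NA = unknown
  placed <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[(is.na(sidx[remaining]) | placed[sidx[remaining]]) &
                       (is.na(didx[remaining]) | placed[didx[remaining]])]
    if (!length(ready))
      stop("pedigree contains a cycle (an animal is its own ancestor)")
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  newpos <- match(seq_len(n), order_out)  # old row -> new position
  sire <- ifelse(is.na(sidx), 0L, newpos[sidx])[order_out]
  dam  <- ifelse(is.na(didx), 0L, newpos[didx])[order_out]
  new("Pedigree", id = an[order_out], sire = as.integer(sire),
      dam = as.integer(dam), generation = gen[order_out])
}

# ---------------------------------------------------------------------------
# SimConfig: the simulated world.
# ---------------------------------------------------------------------------

#' SimConfig: parameters of the simulated selected population
#'
#' Created with [simConfig()]; see that constructor for field semantics and
#' defaults.
#' @export
setClass("SimConfig",
         representation(nGenerations = "integer",
                        foundersPerSex = "integer",
                        offspringPerGeneration = "integer",
                        nChromosomes = "integer",
                        snpsPerChromosome = "integer",
                        chromosomeLengthMorgans = "numeric",
                        nQtl = "integer",
                        qtlVarianceFractions = "numeric",
                        qtlFounderFreq = "numeric",
                        nTraits = "integer",
                        geneticCovariance = "matrix",
                        residualCovariance = "matrix",
                        maternalPeVariance = "numeric",
                        sexEffects = "numeric",
                        cgPerGeneration = "integer",
                        cgSd = "numeric",
                        selectionProportion = "numeric",
                        selectionTraitIndex = "integer",
                        genotypingCountsPerGeneration = "integer",
                        selectiveGenotypingGenerations = "integer",
                        trait2RecordingFraction = "numeric",
                        trait3Threshold = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  spd <- function(S) {
    isTRUE(all.equal(S, t(S))) && all(eigen(S, symmetric = TRUE,
                                            only.values = TRUE)$values > 0)
  }
  if (!spd(object@geneticCovariance))
    msg <- c(msg, "geneticCovariance must be symmetric positive definite")
  if (!spd(object@residualCovariance))
    msg <- c(msg, "residualCovariance must be symmetric positive definite")
  if (length(object@qtlVarianceFractions) != object@nQtl)
    msg <- c(msg, "qtlVarianceFractions must have length nQtl")
  if (object@nQtl > 0 &&
      (any(object@qtlVarianceFractions <= 0) ||
       sum(object@qtlVarianceFractions) >= 1))
    msg <- c(msg, "qtlVarianceFractions must be positive and sum to < 1")
  if (object@selectionProportion <= 0 || object@selectionProportion > 1)
    msg <- c(msg, "selectionProportion must be in (0, 1]")
  if (length(object@genotypingCountsPerGeneration) != object@nGenerations)
    msg <- c(msg, "genotypingCountsPerGeneration must have length nGenerations")
  if (any(object@genotypingCountsPerGeneration >
          object@offspringPerGeneration))
    msg <- c(msg, "genotyping counts cannot exceed generation sizes")
  if (any(object@maternalPeVariance < 0))
    msg <- c(msg, "maternalPeVariance must be non-negative")
  if (object@selectionTraitIndex < 1 ||
      object@selectionTraitIndex > object@nTraits)
    msg <- c(msg, "selectionTraitIndex out of range")
  nT <- object@nTraits
  if (nrow(object@geneticCovariance) != nT ||
      nrow(object@residualCovariance) != nT ||
      length(object@maternalPeVariance) != nT ||
      length(object@sexEffects) != nT)
    msg <- c(msg, "trait-dimensioned fields must match nTraits")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SNPEffectSet: back-solved SNP effects across weighting iterations.
# ---------------------------------------------------------------------------

#' SNPEffectSet: SNP effects, weights and variances per iteration
#'
#' Long-format store of back-solved marker effects.  One row per SNP per
#' weighting iteration, columns `iteration`, `snp`, `chr`, `pos`, `index`,
#' `effect`, `weight`, `freq`, `variance` where
#' `variance = effect^2 * 2 * freq * (1 - freq)`.
#' @slot data data.frame as described.
#' @export
setClass("SNPEffectSet", representation(data = "data.frame"))

setValidity("SNPEffectSet", function(object) {
  d <- object@data
  need <- c("iteration", "snp", "chr", "index", "effect", "weight",
            "freq", "variance")
  msg <- character(0)
  if (!all(need %in% colnames(d)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, colnames(d)), collapse = ", ")))
  else {
    if (any(d$weight <= 0)) msg <- c(msg, "weights must be strictly positive")
    if (any(d$variance < 0)) msg <- c(msg, "variances must be non-negative")
    sums <- tapply(d$weight, d$iteration, sum)
    m <- tapply(d$weight, d$iteration, length)
    if (any(abs(sums - m) > 1e-6 * m))
      msg <- c(msg, "weights must be normalized to sum to the SNP count")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# WindowSet: exclusive tiling of a chromosome-ordered map into SNP windows.
# ---------------------------------------------------------------------------

#' WindowSet: exclusive SNP windows with variance shares
#'
#' A disjoint, exhaustive tiling of every chromosome into windows of at most
#' `windowSize` SNPs, each carrying the sum of per-SNP variances inside it and
#' its percent of the total SNP variance.  Window variances conserve the total
#' per-SNP variance by construction; validity enforces disjointness, coverage
#' and conservation.
#'
#' @slot data data.frame with columns `chr`, `start`, `end` (map indices,
#'   1-based within chromosome block as given by the map order), `firstSnp`,
#'   `lastSnp`, `nSnps`, `variance`, `pct`.
#' @slot totalVariance numeric, the denominator of `pct` (sum of all per-SNP
#'   variances).
#' @slot windowSize integer, nominal window size n.
#' @export
setClass("WindowSet",
         representation(data = "data.frame", totalVariance = "numeric",
                        windowSize = "integer"))

setValidity("WindowSet", function(object) {
  d <- object@data
  msg <- character(0)
  need <- c("chr", "start", "end", "nSnps", "variance", "pct")
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(d)), collapse = ", ")))
  if (any(d$end < d$start)) msg <- c(msg, "window end before start")
  if (any(d$nSnps > object@windowSize))
    msg <- c(msg, "window larger than windowSize")
  for (ch in unique(d$chr)) {
    w <- d[d$chr == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] != w$end[-nrow(w)] + 1)) {
      msg <- c(msg, sprintf("windows on chromosome %s not disjoint/exhaustive", ch))
      break
    }
  }
  tot <- sum(d$variance)
  if (object@totalVariance > 0 &&
      abs(tot - object@totalVariance) > 1e-8 * object@totalVariance)
    msg <- c(msg, "window variances do not conserve the per-SNP total")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# StabilityReport: persistence of top windows across generation scenarios.
# ---------------------------------------------------------------------------

#' StabilityReport: top-window persistence across scenarios
#'
#' One row per window that is in the top k of at least one scenario, with the
#' matched percent of variance in every scenario, the persistence count (in
#' how many scenarios the matched window is itself top-k) and a flag for
#' windows that drop below 0.1% of variance in some other scenario.
#'
#' @slot table data.frame, see [persistenceReport()].
#' @slot scenarios character, scenario names in run order.
#' @slot k integer, the k of "top-k".
#' @export
setClass("StabilityReport",
         representation(table = "data.frame", scenarios = "character",
                        k = "integer"))

setValidity("StabilityReport", function(object) {
  t <- object@table
  if (nrow(t) && ("persistence" %in% colnames(t)) &&
      (any(t$persistence < 1) ||
       any(t$persistence > length(object@scenarios))))
    return("persistence counts must be in [1, number of scenarios]")
  TRUE
})
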