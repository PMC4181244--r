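# Accessors and show methods for the core classes.

#' @rdname GenotypeData
#' @param x a `GenotypeData` object.
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' @describeIn GenotypeData gene content as an animals x SNPs numeric matrix.
#' @export
setMethod("genoMatrix", "GenotypeData", function(x) t(assay(x, "geno")))

#' @rdname GenotypeData
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @describeIn GenotypeData marker map as a data.frame with `snp`, `chr`,
#'   `pos` and the dense map `index` (1..m in map order).
#' @export
setMethod("markerMap", "GenotypeData", function(x) {
  rd <- rowData(x)
  data.frame(snp = rownames(x), chr = as.vector(rd$chr),
             pos = as.vector(rd$pos), index = seq_len(nrow(x)),
             stringsAsFactors = FALSE)
})

#' @rdname GenotypeData
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @describeIn GenotypeData animal ids (column names of the container).
#' @export
setMethod("animalIds", "GenotypeData", function(x) colnames(x))

#' @describeIn GenotypeData number of SNPs.
#' @export
nSnps <- function(x) nrow(x)

#' @describeIn GenotypeData number of animals.
#' @export
nAnimals <- function(x) ncol(x)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "animals x", nrow(object), "SNPs on",
      length(unique(rowData(object)$chr)), "chromosome(s)\n")
  g <- assay(object, "geno")
  miss <- mean(is.na(g))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

# --- Pedigree ---------------------------------------------------------------

#' Pedigree accessors
#'
#' `pedigreeTable()` returns the pedigree as a data.frame with original labels;
#' `nIndividuals()` the number of animals; `generations()` the cohort labels in
#' order of first appearance.
#'
#' @param ped a [Pedigree-class] object.
#' @return `pedigreeTable`: data.frame with columns `animal`, `sire`, `dam`,
#'   `generation` (parents as labels, `NA` unknown).
#' @export
pedigreeTable <- function(ped) {
  lab <- function(i) ifelse(i == 0L, NA_character_, ped@id[pmax(i, 1L)])
  data.frame(animal = ped@id, sire = lab(ped@sire), dam = lab(ped@dam),
             generation = ped@generation, stringsAsFactors = FALSE)
}

#' @rdname pedigreeTable
#' @export
nIndividuals <- function(ped) length(ped@id)

#' @rdname pedigreeTable
#' @export
generations <- function(ped) unique(ped@generation)

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat("Pedigree:", n, "animals,",
      sum(object@sire == 0 & object@dam == 0), "founders\n")
  gen <- table(factor(object@generation,
                      levels = unique(object@generation)))
  cat("  generations:",
      paste(sprintf("%s (%d)", names(gen), gen), collapse = ", "), "\n")
})

# --- SNPEffectSet -----------------------------------------------------------

#' Extract SNP effects for one iteration
#'
#' @param x a [SNPEffectSet-class].
#' @param iteration which weighting iteration (default: the last one).
#' @return data.frame with one row per SNP.
#' @export
snpEffects <- function(x, iteration = NULL) {
  d <- x@data
  if (is.null(iteration)) iteration <- max(d$iteration)
  out <- d[d$iteration == iteration, , drop = FALSE]
  out[order(out$index), , drop = FALSE]
}

#' @rdname snpEffects
#' @export
iterations <- function(x) sort(unique(x@data$iteration))

setMethod("show", "SNPEffectSet", function(object) {
  d <- object@data
  cat("SNPEffectSet:", length(unique(d$snp)), "SNPs,",
      length(unique(d$iteration)), "iterations",
      sprintf("(%s)\n", paste(sort(unique(d$iteration)), collapse = ", ")))
})

# --- WindowSet --------------------------------------------------------------

#' Window table of a WindowSet
#'
#' @param x a [WindowSet-class].
#' @return data.frame of windows in map order.
#' @export
windowTable <- function(x) x@data

#' @rdname windowTable
#' @export
totalSnpVariance <- function(x) x@totalVariance

setMethod("show", "WindowSet", function(object) {
  d <- object@data
  cat("WindowSet:", nrow(d), "exclusive windows (n =", object@windowSize,
      ") over", length(unique(d$chr)), "chromosome(s)\n")
  top <- d[order(-d$variance), , drop = FALSE][1, , drop = FALSE]
  if (nrow(top))
    cat(sprintf("  largest window: chr %s [%d-%d], %.3f%% of SNP variance\n",
                top$chr, top$start, top$end, top$pct))
})

# --- StabilityReport --------------------------------------------------------

#' Table of a StabilityReport
#'
#' @param x a [StabilityReport-class].
#' @return the persistence table (see [persistenceReport()]).
#' @export
reportTable <- function(x) x@table

setMethod("show", "StabilityReport", function(object) {
  t <- object@table
  ns <- length(object@scenarios)
  cat("StabilityReport: ", nrow(t), " windows ever in a top-", object@k,
      " across ", ns, " scenarios\n", sep = "")
  if (nrow(t)) {
    cat("  persistent in all scenarios:", sum(t$persistence == ns), "\n")
    cat("  top in one scenario but < 0.1% in another:",
        sum(t$lowElsewhere), "\n")
  }
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenerations, "generations x",
      object@offspringPerGeneration, "offspring;",
      object@nChromosomes * object@snpsPerChromosome, "SNPs;",
      object@nQtl, "QTL;", object@nTraits, "traits; selection p =",
      object@selectionProportion, "\n")
})
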