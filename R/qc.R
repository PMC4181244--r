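# Genotype quality control: monomorphic SNPs, SNP call rate, minor allele
# frequency, then animal call rate — a single deterministic pass.  Thresholds
# are strict ("< 0.05" removes, exactly 0.05 survives), matching the usual
# reading of chip QC reports.

#' QC thresholds
#'
#' @param minMaf minimum minor allele frequency (strict: MAF < `minMaf` is
#'   removed, default 0.05).
#' @param minSnpCallRate,minAnimalCallRate minimum call rates (strict,
#'   default 0.9).
#' @param dropMonomorphic remove SNPs with a single observed allele.
#' @return A list of class `QCThresholds`.
#' @export
qcThresholds <- function(minMaf = 0.05, minSnpCallRate = 0.9,
                         minAnimalCallRate = 0.9, dropMonomorphic = TRUE) {
  stopifnot(minMaf >= 0, minMaf <= 1, minSnpCallRate >= 0,
            minSnpCallRate <= 1, minAnimalCallRate >= 0,
            minAnimalCallRate <= 1)
  structure(list(minMaf = minMaf, minSnpCallRate = minSnpCallRate,
                 minAnimalCallRate = minAnimalCallRate,
                 dropMonomorphic = dropMonomorphic),
            class = "QCThresholds")
}

#' Observed allele frequencies
#'
#' Frequency of the counted (second) allele per SNP: mean gene content over
#' non-missing calls divided by 2.
#'
#' @param g a [GenotypeData-class] or an animals x SNPs matrix.
#' @return Named numeric vector of frequencies.
#' @export
alleleFrequencies <- function(g) {
  gm <- if (is(g, "GenotypeData")) genoMatrix(g) else as.matrix(g)
  nOk <- colSums(!is.na(gm))
  if (any(nOk == 0))
    stop("SNP(s) with no non-missing call: ",
         paste(head(colnames(gm)[nOk == 0], 5), collapse = ", "))
  colMeans(gm, na.rm = TRUE) / 2
}

#' Apply genotype quality control
#'
#' Filter order: monomorphic SNPs, SNP call rate, MAF (computed on
#' non-missing calls), then animal call rate on the surviving SNPs.  Each SNP
#' is removed under the first rule it triggers, so the report's by-reason
#' counts partition the input.
#'
#' @param g a [GenotypeData-class].
#' @param thresholds a [qcThresholds()] list.
#' @return List with `geno` (filtered [GenotypeData-class]) and `report`, a
#'   list holding `snpsRemoved` / `animalsRemoved` data.frames (id, reason,
#'   value) and a `counts` summary.
#' @export
applyQC <- function(g, thresholds = qcThresholds()) {
  stopifnot(is(g, "GenotypeData"))
  gm <- genoMatrix(g)
  n <- nrow(gm)
  snpReason <- setNames(rep(NA_character_, ncol(gm)), colnames(gm))
  snpValue <- setNames(rep(NA_real_, ncol(gm)), colnames(gm))

  nOk <- colSums(!is.na(gm))
  p <- ifelse(nOk > 0, colMeans(gm, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(p, 1 - p)
  callRate <- nOk / n

  if (thresholds$dropMonomorphic) {
    mono <- is.na(snpReason) & (nOk == 0 | p == 0 | p == 1)
    snpReason[mono] <- "monomorphic"; snpValue[mono] <- p[mono]
  }
  low <- is.na(snpReason) & callRate < thresholds$minSnpCallRate
  snpReason[low] <- "snp_call_rate"; snpValue[low] <- callRate[low]
  lowMaf <- is.na(snpReason) & maf < thresholds$minMaf
  snpReason[lowMaf] <- "maf"; snpValue[lowMaf] <- maf[lowMaf]

  keepSnp <- is.na(snpReason)
  if (!any(keepSnp)) stop("QC removed every SNP")

  sub <- gm[, keepSnp, drop = FALSE]
  aRate <- rowSums(!is.na(sub)) / ncol(sub)
  keepAn <- aRate >= thresholds$minAnimalCallRate
  if (!any(keepAn)) stop("QC removed every animal")

  out <- GenotypeData(sub[keepAn, , drop = FALSE],
                      markerMap(g)[keepSnp, c("snp", "chr", "pos")])
  report <- list(
    snpsRemoved = data.frame(snp = names(snpReason)[!keepSnp],
                             reason = snpReason[!keepSnp],
                             value = snpValue[!keepSnp],
                             row.names = NULL, stringsAsFactors = FALSE),
    animalsRemoved = data.frame(animal = rownames(gm)[!keepAn],
                                reason = rep("animal_call_rate", sum(!keepAn)),
                                value = aRate[!keepAn],
                                row.names = NULL, stringsAsFactors = FALSE),
    counts = c(snpsIn = ncol(gm), snpsOut = sum(keepSnp),
               animalsIn = n, animalsOut = sum(keepAn)))
  list(geno = out, report = report)
}
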