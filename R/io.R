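# Readers/writers for the standard plain-text formats: PLINK-style PED/MAP,
# an additive-coded 0/1/2 genotype CSV, pedigree CSV and phenotype CSV.
# Gene content counts the map-defined second allele (A2); the writer emits
# 1/2 allele coding so round-trips are exact.

#' Read genotypes from PLINK-style PED/MAP files
#'
#' PED: whitespace-delimited, columns FID IID PAT MAT SEX PHENO followed by
#' two allele columns per SNP ("0 0" = missing call).  MAP: chromosome, SNP
#' id, genetic position, base-pair position, optionally a 5th and 6th column
#' naming alleles A1 and A2; gene content is the count of A2.  Without the
#' allele columns the counted allele is "2" under 1/2 coding, otherwise the
#' lexicographically larger allele observed at the SNP.
#'
#' @param pedPath,mapPath file paths.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypesPed <- function(pedPath, mapPath) {
  if (!file.exists(pedPath)) stop("PED file not found: ", pedPath)
  if (!file.exists(mapPath)) stop("MAP file not found: ", mapPath)
  mp <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("MAP file must have at least 4 columns")
  map <- data.frame(snp = as.character(mp[[2]]), chr = mp[[1]],
                    pos = as.numeric(mp[[4]]), stringsAsFactors = FALSE)
  m <- nrow(map)
  fields <- count.fields(pedPath)
  bad <- which(fields != 6 + 2 * m)
  if (length(bad))
    stop("malformed PED rows (expected ", 6 + 2 * m, " fields): lines ",
         paste(head(bad, 5), collapse = ", "))
  ped <- read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  ids <- ped[[2]]
  if (anyDuplicated(ids))
    stop("duplicate animal ids in PED: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  counted <- if (ncol(mp) >= 6) as.character(mp[[6]]) else
    vapply(seq_len(m), function(j) {
      al <- setdiff(unique(c(a1[, j], a2[, j])), "0")
      if (!length(al)) "2" else sort(al)[length(al)]
    }, character(1))
  geno <- matrix(NA_real_, length(ids), m,
                 dimnames = list(ids, map$snp))
  for (j in seq_len(m)) {
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
    geno[miss, j] <- NA_real_
  }
  GenotypeData(geno, map)
}

#' Write genotypes as PLINK-style PED/MAP
#'
#' Alleles are coded 1/2 with gene content = count of allele "2"; the MAP file
#' carries A1/A2 columns ("1" and "2") so the counted allele is explicit.
#'
#' @param g a [GenotypeData-class].
#' @param pedPath,mapPath output paths.
#' @export
writeGenotypesPed <- function(g, pedPath, mapPath) {
  map <- markerMap(g)
  write.table(data.frame(map$chr, map$snp, 0, map$pos, "1", "2"),
              mapPath, quote = FALSE, row.names = FALSE, col.names = FALSE)
  gm <- genoMatrix(g)
  n <- nrow(gm); m <- ncol(gm)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    v <- gm[, j]
    al[, 2 * j - 1] <- ifelse(is.na(v), "0", ifelse(v >= 1, "2", "1"))
    al[, 2 * j]     <- ifelse(is.na(v), "0", ifelse(v == 2, "2", "1"))
  }
  out <- cbind("FAM", rownames(gm), "0", "0", "0", "-9", al)
  write.table(out, pedPath, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(NULL)
}

#' Read/write genotypes as additive-coded CSV
#'
#' Genotype CSV: first column `animal`, one column per SNP with values
#' 0/1/2/NA.  Map CSV: columns `snp`, `chr`, `pos`.
#'
#' @param genoPath,mapPath file paths.
#' @return `readGenotypesCsv`: a [GenotypeData-class].
#' @export
readGenotypesCsv <- function(genoPath, mapPath) {
  if (!file.exists(genoPath)) stop("genotype CSV not found: ", genoPath)
  if (!file.exists(mapPath)) stop("map CSV not found: ", mapPath)
  d <- read.table(genoPath, header = TRUE, sep = ",",
                  stringsAsFactors = FALSE, check.names = FALSE)
  map <- read.table(mapPath, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  if (colnames(d)[1] != "animal") stop("first genotype CSV column must be 'animal'")
  ids <- as.character(d$animal)
  if (anyDuplicated(ids))
    stop("duplicate animal ids in genotype CSV")
  geno <- as.matrix(d[, -1, drop = FALSE])
  rownames(geno) <- ids
  GenotypeData(geno, map)
}

#' @rdname readGenotypesCsv
#' @param g a [GenotypeData-class].
#' @export
writeGenotypesCsv <- function(g, genoPath, mapPath) {
  gm <- genoMatrix(g)
  d <- data.frame(animal = rownames(gm), gm, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, genoPath, quote = FALSE, sep = ",", row.names = FALSE)
  write.table(markerMap(g)[, c("snp", "chr", "pos")], mapPath,
              quote = FALSE, sep = ",", row.names = FALSE)
  invisible(NULL)
}

#' Read/write a pedigree CSV
#'
#' Columns `animal`, `sire`, `dam` and optionally `generation`; unknown
#' parents as empty, `0` or `NA`.  Rows may list parents after offspring;
#' they are renumbered and topologically reordered on read.
#'
#' @param path file path.
#' @return `readPedigree`: a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% colnames(d)))
    stop("pedigree CSV must have columns animal, sire, dam")
  Pedigree(d)
}

#' @rdname readPedigree
#' @param ped a [Pedigree-class].
#' @export
writePedigree <- function(ped, path) {
  write.table(pedigreeTable(ped), path, quote = FALSE, sep = ",",
              row.names = FALSE, na = "")
  invisible(NULL)
}

#' Read/write a phenotype CSV
#'
#' Header row with `animal` plus fixed-effect / dam / generation / trait
#' columns; empty fields are missing records.  Duplicate animal ids are fatal.
#'
#' @param path file path.
#' @return `readPhenotypes`: a data.frame.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!"animal" %in% colnames(d)) stop("phenotype CSV must have column 'animal'")
  d$animal <- as.character(d$animal)
  if (anyDuplicated(d$animal))
    stop("duplicate animal ids in phenotype table: line(s) ",
         paste(head(which(duplicated(d$animal)) + 1L, 5), collapse = ", "))
  d
}

#' @rdname readPhenotypes
#' @param phen phenotype data.frame.
#' @export
writePhenotypes <- function(phen, path) {
  write.table(phen, path, quote = FALSE, sep = ",", row.names = FALSE, na = "")
  invisible(NULL)
}
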