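# Generation-subset scenarios and persistence of top windows.  The four
# canonical scenarios use the complete data and the three sliding
# three-generation subsets; the pedigree is always complete, only phenotypes
# and genotypes are filtered, and allele frequencies (hence G) are recomputed
# on each scenario's genotyped set.

#' Scenario specification
#'
#' @param name scenario label.
#' @param phenGenerations,genoGenerations generation labels whose phenotypes /
#'   genotypes enter the analysis.
#' @return List of class `ScenarioSpec`.
#' @export
scenarioSpec <- function(name, phenGenerations, genoGenerations = phenGenerations) {
  structure(list(name = name, phenGenerations = as.character(phenGenerations),
                 genoGenerations = as.character(genoGenerations)),
            class = "ScenarioSpec")
}

#' The four canonical scenarios
#'
#' Complete data, then the sliding subsets G1-G3, G2-G4, G3-G5 (generalised
#' to any number of generations >= 3: all, then every three-generation
#' window).
#'
#' @param generationLabels cohort labels in order, default G1..G5.
#' @return Named list of [scenarioSpec()] objects.
#' @export
canonicalScenarios <- function(generationLabels = paste0("G", 1:5)) {
  g <- generationLabels
  out <- list(scenarioSpec("ALL", g))
  if (length(g) >= 3)
    for (s in seq_len(length(g) - 2)) {
      sub <- g[s:(s + 2)]
      out[[length(out) + 1L]] <-
        scenarioSpec(paste0(sub[1], "-", sub[3]), sub)
    }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Filter data to a scenario
#'
#' Phenotypes are restricted to the scenario's phenotype generations and the
#' genotyped-animal set to its genotype generations; the pedigree is never
#' touched.  Generation labels are taken from the phenotype table (and from
#' the pedigree for genotyped animals without a phenotype row).
#'
#' @param phen phenotype data.frame with a `generation` column.
#' @param genotypedIds character vector of genotyped animal ids.
#' @param spec a [scenarioSpec()].
#' @param ped a [Pedigree-class] supplying generation labels for ids absent
#'   from `phen`.
#' @return List with `phen` and `genotypedIds`.
#' @export
subsetScenario <- function(phen, genotypedIds, spec, ped = NULL) {
  stopifnot(inherits(spec, "ScenarioSpec"), "generation" %in% colnames(phen))
  phenSub <- phen[phen$generation %in% spec$phenGenerations, , drop = FALSE]
  gen <- phen$generation[match(genotypedIds, phen$animal)]
  if (anyNA(gen) && !is.null(ped))
    gen[is.na(gen)] <- ped@generation[match(genotypedIds[is.na(gen)], ped@id)]
  keep <- !is.na(gen) & gen %in% spec$genoGenerations
  if (!any(keep))
    stop("scenario '", spec$name, "' has no genotyped animals")
  if (!nrow(phenSub))
    stop("scenario '", spec$name, "' has no phenotype records")
  list(phen = phenSub, genotypedIds = genotypedIds[keep])
}

#' Match windows across two tilings
#'
#' Two windows match when their SNP-index ranges on the shared map overlap by
#' at least one SNP (default) or reciprocally by at least 50% of each
#' window's length.
#'
#' @param wsA,wsB [WindowSet-class] objects over the same marker map.
#' @param rule `"any"` or `"reciprocal50"`.
#' @return data.frame of matched pairs: `chrA` row index in A, row index in
#'   B, chromosome, and the overlap in SNPs.
#' @export
windowMatching <- function(wsA, wsB, rule = c("any", "reciprocal50")) {
  rule <- match.arg(rule)
  a <- wsA@data; b <- wsB@data
  out <- list()
  for (i in seq_len(nrow(a))) {
    bb <- which(b$chr == a$chr[i])
    if (!length(bb)) next
    ov <- pmin(a$end[i], b$end[bb]) - pmax(a$start[i], b$start[bb]) + 1L
    ok <- ov >= 1L
    if (rule == "reciprocal50") {
      lenA <- a$end[i] - a$start[i] + 1L
      lenB <- b$end[bb] - b$start[bb] + 1L
      ok <- ok & (ov >= 0.5 * lenA) & (ov >= 0.5 * lenB)
    }
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        rowA = i, rowB = bb[ok], chr = a$chr[i], overlap = ov[ok])
  }
  if (!length(out))
    return(data.frame(rowA = integer(0), rowB = integer(0),
                      chr = character(0), overlap = integer(0)))
  do.call(rbind, out)
}

#' Persistence of top windows across scenarios
#'
#' For every window that is in the top k of at least one scenario, find the
#' best-matching window (largest overlap, leftmost on ties) in every other
#' scenario and record its percent of variance; count the scenarios in which
#' the matched window is itself top-k; and flag windows that are top in one
#' scenario but explain < `lowPct` percent in some other.
#'
#' Windows from per-scenario QC may live on per-scenario maps; supply
#' `referenceMap` to re-express every window's span in reference map indices
#' (via its first/last SNP ids) before matching.
#'
#' @param windowSets named list of [WindowSet-class], one per scenario.
#' @param k top-k (default 10).
#' @param lowPct threshold for the "low elsewhere" flag (default 0.1).
#' @param referenceMap optional map (`snp`, `chr`, `pos`) shared by all
#'   scenarios' SNPs.
#' @return A [StabilityReport-class]; its table has one row per distinct top
#'   window with columns `chr`, `start`, `end`, `topIn`, `persistence`,
#'   `lowElsewhere` and one `pct_<scenario>` column per scenario.
#' @export
persistenceReport <- function(windowSets, k = 10L, lowPct = 0.1,
                              referenceMap = NULL) {
  stopifnot(length(windowSets) >= 2)
  if (is.null(names(windowSets)) || any(names(windowSets) == ""))
    names(windowSets) <- paste0("scenario", seq_along(windowSets))
  scen <- names(windowSets)
  tabs <- lapply(windowSets, function(ws) {
    d <- ws@data
    if (!is.null(referenceMap)) {
      d$start <- match(d$firstSnp, referenceMap$snp)
      d$end <- match(d$lastSnp, referenceMap$snp)
      if (anyNA(d$start) || anyNA(d$end))
        stop("window SNP ids missing from the reference map")
    }
    d$rank <- rank(-d$variance, ties.method = "first")
    d
  })
  # union of top-k windows, deduplicated by overlap on the shared coordinates
  top <- list()
  for (s in scen) {
    tk <- tabs[[s]][tabs[[s]]$rank <= k, , drop = FALSE]
    for (i in seq_len(nrow(tk))) {
      dup <- FALSE
      for (w in top)
        if (w$chr == tk$chr[i] && tk$start[i] <= w$end &&
            tk$end[i] >= w$start) { dup <- TRUE; break }
      if (!dup)
        top[[length(top) + 1L]] <- list(chr = tk$chr[i], start = tk$start[i],
                                        end = tk$end[i], topIn = s)
    }
  }
  rows <- lapply(top, function(w) {
    pct <- setNames(numeric(length(scen)), scen)
    isTop <- setNames(logical(length(scen)), scen)
    for (s in scen) {
      d <- tabs[[s]]
      cand <- which(d$chr == w$chr & d$start <= w$end & d$end >= w$start)
      if (!length(cand)) { pct[s] <- 0; next }
      ov <- pmin(w$end, d$end[cand]) - pmax(w$start, d$start[cand]) + 1L
      best <- cand[order(-ov, d$start[cand])][1]
      pct[s] <- d$pct[best]
      isTop[s] <- d$rank[best] <= k
    }
    out <- data.frame(chr = w$chr, start = w$start, end = w$end,
                      topIn = w$topIn, persistence = sum(isTop),
                      lowElsewhere = any(isTop) && any(pct[!isTop] < lowPct),
                      stringsAsFactors = FALSE)
    for (s in scen) out[[paste0("pct_", s)]] <- pct[s]
    out
  })
  rep <- new("StabilityReport", table = do.call(rbind, rows),
             scenarios = scen, k = as.integer(k))
  validObject(rep)
  rep
}

#' Independent chromosome segments
#'
#' `q = 2 Ne L / ln(4 Ne L)`, rounded to the nearest integer: the expected
#' number of independently segregating chromosome segments for effective
#' population size `Ne` and total genetic map length `L` Morgans (natural
#' log).
#'
#' @param Ne effective population size (> 0).
#' @param L genome length in Morgans (> 0).
#' @param round round to integer for reporting (default TRUE).
#' @return Number of segments.
#' @export
qSegments <- function(Ne, L, round = TRUE) {
  stopifnot(Ne > 0, L > 0)
  q <- 2 * Ne * L / log(4 * Ne * L)
  if (round) round(q) else q
}
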