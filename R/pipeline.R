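# End-to-end orchestration: simulate (or load) -> QC -> relationship
# matrices -> multi-trait ssGBLUP -> back-solved SNP effects with weight
# iterations -> exclusive windows -> cross-scenario stability report.
# Every scenario re-runs QC, allele frequencies, G*, the mixed model and the
# weight iterations from scratch on its own generation subset; the pedigree
# is always complete.

#' Pipeline run configuration
#'
#' @param sim a [SimConfig-class]; used when no input paths are given.
#' @param paths optional named list (`geno`, `map`, `pedigree`, `phenotypes`)
#'   of CSV inputs replacing simulation (genotype CSV dialect of
#'   [readGenotypesCsv()]).
#' @param qc a [qcThresholds()] list.
#' @param G0,R0,P0 variance components for the mixed model; default: the
#'   simulation's true values.
#' @param traits trait columns to analyse; default: all simulated traits.
#' @param windowSize,topK,nIter window size n, top-k, weight iterations.
#' @param scenarios list of [scenarioSpec()]; default: the four canonical
#'   generation subsets.
#' @param blend G*/A22 blending fraction.
#' @param solver,solverTol mixed-model solver and PCG tolerance.
#' @param seed run seed (overrides `sim@seed` so one seed fixes the run).
#' @param outDir output directory (created); `NULL` = no files written.
#' @param writePlots write per-scenario Manhattan PNGs.
#' @return List of class `RunConfig`.
#' @export
runConfig <- function(sim = simConfig(), paths = NULL, qc = qcThresholds(),
                      G0 = NULL, R0 = NULL, P0 = NULL, traits = NULL,
                      windowSize = 20L, topK = 10L, nIter = 3L,
                      scenarios = NULL, blend = 0.05,
                      solver = c("pcg", "direct"), solverTol = 1e-10,
                      seed = sim@seed, outDir = NULL, writePlots = FALSE) {
  structure(list(sim = sim, paths = paths, qc = qc, G0 = G0, R0 = R0,
                 P0 = P0, traits = traits, windowSize = as.integer(windowSize),
                 topK = as.integer(topK), nIter = as.integer(nIter),
                 scenarios = scenarios, blend = blend,
                 solver = match.arg(solver), solverTol = solverTol,
                 seed = as.integer(seed), outDir = outDir,
                 writePlots = writePlots),
            class = "RunConfig")
}

# serializable view of a RunConfig (S4 sim flattened to a plain list)
.configAsList <- function(config) {
  sim <- config$sim
  simList <- lapply(slotNames(sim), function(s) slot(sim, s))
  names(simList) <- slotNames(sim)
  out <- config
  out$sim <- simList
  out$scenarios <- lapply(out$scenarios, unclass)
  class(out) <- NULL
  out
}

# One scenario: QC on the scenario's genotyped set, frequencies, G*, MME,
# weight iterations, windows.  Returns window sets per trait plus
# bookkeeping.
.runScenario <- function(spec, phen, geno, genotypedIds, ped, Ainv, model,
                         config, log = message) {
  sub <- subsetScenario(phen, genotypedIds, spec, ped)
  gSub <- geno[, intersect(animalIds(geno), sub$genotypedIds)]
  gSub <- as(gSub, "GenotypeData")
  qcRes <- applyQC(gSub, config$qc)
  gQC <- qcRes$geno
  gids <- animalIds(gQC)
  log(sprintf("[%s] phenotypes %d, genotyped %d (QC kept %d/%d SNPs)",
              spec$name, nrow(sub$phen), length(gids),
              ncol(genoMatrix(gQC)), nSnps(gSub)))
  p <- alleleFrequencies(gQC)
  G <- buildG(gQC, p = p)
  A22 <- extractA22(Ainv, gids)
  Gstar <- tuneAndBlendG(G, A22, blend = config$blend)$G
  Hinv <- buildHInverse(Ainv, A22, Gstar, gids)
  fit <- fitSSGBLUP(model, sub$phen, ped, Hinv, method = config$solver,
                    tol = config$solverTol)
  log(sprintf("[%s] MME solved (%s iterations)", spec$name,
              as.character(fit$convergence$iterations)))
  Zg <- genoMatrix(gQC)
  map <- markerMap(gQC)
  Z <- sweep(Zg, 2L, 2 * p, "-")
  Z[is.na(Z)] <- 0
  perTrait <- lapply(model$traits, function(tr) {
    ag <- fit$gebv[gids, tr]
    eff <- iterateWeights(Z, ag, p, nIter = config$nIter, A22 = A22,
                          blend = config$blend, map = map)
    final <- snpEffects(eff)
    ws <- windowVariances(final$variance, map, n = config$windowSize)
    list(effects = eff, windows = ws)
  })
  names(perTrait) <- model$traits
  list(spec = spec, fit = fit, perTrait = perTrait, map = map,
       qcReport = qcRes$report, genotypedIds = gids)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config seed.  When `outDir` is set, writes the
#' config copy (JSON), per-trait summary, SNP effect and window CSVs keyed by
#' (scenario, trait, iteration), the stability report, and a run log; a
#' failure leaves `ERROR.json` in the output directory.
#'
#' @param config a [runConfig()].
#' @return Invisible list: `data` (pedigree, genotypes, phenotypes, truth if
#'   simulated), `scenarios` (per-scenario fits and window sets), `stability`
#'   (named per-trait list of [StabilityReport-class]), `summary` (per-trait
#'   n/mean/sd table).
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outDir
  logLines <- character(0)
  log <- function(msg) {
    logLines <<- c(logLines, msg)
    message(msg)
  }
  run <- function() {
    if (is.null(config$paths)) {
      sim <- config$sim
      sim@seed <- config$seed
      log(sprintf("simulating population (seed %d)", config$seed))
      simOut <- simulatePopulation(sim)
      ped <- simOut$pedigree
      geno <- simOut$geno
      phen <- simOut$phenotypes
      truth <- simOut$truth
      genotypedIds <- assignGenotyped(ped, phen, sim, seed = config$seed)
      G0 <- if (is.null(config$G0)) sim@geneticCovariance else config$G0
      R0 <- if (is.null(config$R0)) sim@residualCovariance else config$R0
      P0 <- if (is.null(config$P0)) {
        if (any(sim@maternalPeVariance > 0))
          diag(sim@maternalPeVariance, sim@nTraits) else NULL
      } else config$P0
      traits <- if (is.null(config$traits)) .traitNames(sim@nTraits)
                else config$traits
    } else {
      for (p in unlist(config$paths))
        if (!file.exists(p)) stop("input file not found: ", p)
      log("loading inputs")
      geno <- readGenotypesCsv(config$paths$geno, config$paths$map)
      ped <- readPedigree(config$paths$pedigree)
      phen <- readPhenotypes(config$paths$phenotypes)
      truth <- NULL
      genotypedIds <- animalIds(geno)
      G0 <- config$G0; R0 <- config$R0; P0 <- config$P0
      if (is.null(G0) || is.null(R0))
        stop("G0 and R0 must be supplied when loading external data")
      traits <- if (is.null(config$traits))
        setdiff(colnames(phen), c("animal", "generation", "sex", "cg", "dam"))
        else config$traits
    }
    model <- modelSpec(traits, G0, R0, P0)
    summaryTab <- summarizeSimulation(phen, traits)
    log(paste(capture.output(print(summaryTab)), collapse = "\n"))
    scen <- config$scenarios
    if (is.null(scen)) {
      gl <- unique(phen$generation)
      scen <- canonicalScenarios(gl)
    }
    log(sprintf("building A inverse over %d animals", nIndividuals(ped)))
    Ainv <- buildAInverse(ped)
    runs <- lapply(scen, function(sp)
      .runScenario(sp, phen, geno, genotypedIds, ped, Ainv, model, config,
                   log = log))
    names(runs) <- vapply(scen, `[[`, character(1), "name")
    refMap <- markerMap(geno)
    stability <- lapply(traits, function(tr) {
      ws <- lapply(runs, function(r) r$perTrait[[tr]]$windows)
      persistenceReport(ws, k = config$topK, referenceMap = refMap)
    })
    names(stability) <- traits
    result <- list(data = list(pedigree = ped, geno = geno, phenotypes = phen,
                               truth = truth, genotypedIds = genotypedIds),
                   scenarios = runs, stability = stability,
                   summary = summaryTab, config = config)
    if (!is.null(out)) .writePipelineOutputs(result, out, logLines)
    result
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    res <- tryCatch(run(), error = function(e) {
      jsonlite::write_json(list(error = conditionMessage(e)),
                           file.path(out, "ERROR.json"), auto_unbox = TRUE)
      stop(e)
    })
  } else res <- run()
  invisible(res)
}

.writePipelineOutputs <- function(result, out, logLines) {
  config <- result$config
  jsonlite::write_json(.configAsList(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write.table(result$summary, file.path(out, "trait_summary.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  effRows <- list(); winRows <- list()
  for (sn in names(result$scenarios)) {
    r <- result$scenarios[[sn]]
    for (tr in names(r$perTrait)) {
      ed <- r$perTrait[[tr]]$effects@data
      ed <- data.frame(scenario = sn, trait = tr, ed,
                       stringsAsFactors = FALSE)
      effRows[[length(effRows) + 1L]] <- ed
      wd <- windowTable(r$perTrait[[tr]]$windows)
      winRows[[length(winRows) + 1L]] <-
        data.frame(scenario = sn, trait = tr, wd, stringsAsFactors = FALSE)
      if (isTRUE(config$writePlots)) {
        grDevices::png(file.path(out, sprintf("manhattan_%s_%s.png", tr, sn)),
                       width = 900, height = 400)
        plotWindowVariances(r$perTrait[[tr]]$windows, k = config$topK,
                            main = sprintf("%s - %s", tr, sn))
        grDevices::dev.off()
      }
    }
  }
  write.table(do.call(rbind, effRows), file.path(out, "snp_effects.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  write.table(do.call(rbind, winRows), file.path(out, "windows.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  stabRows <- lapply(names(result$stability), function(tr)
    data.frame(trait = tr, reportTable(result$stability[[tr]]),
               stringsAsFactors = FALSE))
  write.table(do.call(rbind, stabRows), file.path(out, "stability.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  txt <- unlist(lapply(names(result$stability), function(tr) {
    rep <- result$stability[[tr]]
    t <- reportTable(rep)
    ns <- length(rep@scenarios)
    c(sprintf("trait %s: %d windows ever top-%d; %d persistent in all %d scenarios; %d top-in-one but <0.1%% elsewhere",
              tr, nrow(t), rep@k, sum(t$persistence == ns), ns,
              sum(t$lowElsewhere)))
  }))
  writeLines(c(txt, "", logLines), file.path(out, "summary.txt"))
  invisible(NULL)
}
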