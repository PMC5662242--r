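#' Run the full landscape-genetic analysis chain
#'
#' End-to-end driver: genotype filtering (missingness, HWE, call rate,
#' MAF, physical thinning), Loiselle kinship with full-sibling pruning,
#' individual (Rousset's a) and site (Nei's D) genetic distances with a
#' one-level AMOVA, landscape isolation variables and barrier matrices,
#' a Mantel / partial-Mantel table, two dbRDA models built by forward
#' selection on adjusted R-squared (one with geographic eigenvectors as
#' explanatory terms, one with geography partialled out), and optionally
#' the IBD-only Type-I-error screen. Every stage is a pure function of its
#' inputs and the seed; artifacts are written as CSV/JSON when `outDir` is
#' given, plus a JSON-lines log with one record per stage.
#'
#' @param genotypes a [GenotypeMatrix-class]; alternatively give `vcf` (and
#'   `meta`) paths
#' @param vcf,meta VCF path and metadata CSV path (see
#'   [readSampleMetadata()]), used when `genotypes` is NULL
#' @param landscape optional [LandscapeModel-class]; when NULL the
#'   landscape stages are skipped
#' @param barrierCodes named list of named vectors site -> integer tier
#'   (e.g. `list(HighwayBarriers = c(S1 = 0, S2 = 1, ...))`)
#' @param maxMissing,hweAlpha,minCallRate,minMaf,thinBp filtering settings
#' @param fsThreshold,hsThreshold kinship classification boundaries
#' @param nPerm permutations for Mantel/AMOVA/dbRDA (default 999)
#' @param pcsPerMatrix spatial eigenvectors used per matrix term (default 2)
#' @param alpha significance level for conditioning-eigenvector selection
#' @param type1 run the Type-I-error suite (default FALSE)
#' @param type1Config [SimulationConfig-class] for the suite; required when
#'   `type1 = TRUE`
#' @param type1Sims simulations in the suite (default 100)
#' @param outDir optional artifact directory
#' @param seed master seed
#' @return list of stage results (filtered genotypes, kinship calls,
#'   retained ids, distance matrices, AMOVA, Mantel table, dbRDA fits,
#'   optional Type-I report)
#' @export
runFullAnalysis <- function(genotypes = NULL, vcf = NULL, meta = NULL,
                            landscape = NULL, barrierCodes = list(),
                            maxMissing = 0.2, hweAlpha = 0.05,
                            minCallRate = 0.75, minMaf = 0.05,
                            thinBp = 250000L,
                            fsThreshold = 0.1875, hsThreshold = 0.09375,
                            nPerm = 999L, pcsPerMatrix = 2L, alpha = 0.05,
                            type1 = FALSE, type1Config = NULL,
                            type1Sims = 100L, outDir = NULL, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  stage <- function(name, value) {
    log[[length(log) + 1]] <<- list(stage = name, seed = seed,
                                    wallTime = proc.time()[["elapsed"]] - t0)
    value
  }
  if (is.null(genotypes)) {
    if (is.null(vcf)) stop("either genotypes or vcf must be given")
    md <- if (!is.null(meta)) {
      if (is.character(meta)) readSampleMetadata(meta) else meta
    } else NULL
    genotypes <- readGenotypeVcf(vcf, md)
  }
  g <- filterIndividuals(genotypes, maxMissing)
  g <- filterLoci(g, hweAlpha, minCallRate, minMaf)
  g <- thinByDistance(g, thinBp)
  g <- stage("filter", g)

  k <- loiselleKinship(g)
  calls <- classifyKinshipPairs(k, fsThreshold, hsThreshold,
                                siteMap = siteOf(g), coords = coordsOf(g))
  retained <- pruneFullSibGroups(calls, missingnessOf(g), individualIds(g))
  gP <- stage("kinship", g[, retained])

  aM <- roussetA(gP)
  dM <- neiD(gP)
  am <- amova(aM, siteOf(gP), nPerm = nPerm, seed = seed)
  stage("distances", NULL)

  xy <- coordsOf(gP)
  geoD <- PairwiseMatrix(as.matrix(dist(xy)), kind = "geographic",
                         labels = rownames(xy))
  logGeo <- PairwiseMatrix(log(as.matrix(geoD) + 1), kind = "geographic")

  varMats <- list()
  if (!is.null(landscape)) {
    sites <- siteOf(gP)
    if (nrow(landscape@ports))
      varMats$PortIsolation <- additivePairMatrix(
        setNames(portIsolation(xy, landscape@ports), rownames(xy)), sites)
    if (length(landscape@rivers))
      varMats$RiverIsolation <- additivePairMatrix(
        setNames(riverIsolation(xy, landscape@rivers), rownames(xy)), sites)
    if (length(landscape@highways))
      varMats$HighwayIsolation <- additivePairMatrix(
        setNames(highwayIsolation(xy, landscape@highways,
                                  width = landscape@highwayWidth),
                 rownames(xy)), sites)
    for (nm in names(barrierCodes)) {
      codes <- setNames(barrierCodes[[nm]][sites], rownames(xy))
      varMats[[nm]] <- barrierPairMatrix(codes)
    }
  }
  stage("landscape", NULL)

  mantelRow <- function(v) {
    mA <- mantelTest(aM, v, nPerm = nPerm, seed = seed)
    mG <- mantelTest(v, logGeo, nPerm = nPerm, seed = seed)
    pM <- partialMantelTest(aM, v, logGeo, nPerm = nPerm, seed = seed)
    c(r = mA@r, p = mA@p, rDistance = mG@r,
      rPartial = pM@r, pPartial = pM@p)
  }
  tab <- lapply(varMats, mantelRow)
  ibd <- mantelTest(aM, logGeo, nPerm = nPerm, seed = seed)
  tab$Distance <- c(r = ibd@r, p = ibd@p, rDistance = NA,
                    rPartial = NA, pPartial = NA)
  mantelTable <- data.frame(variable = names(tab),
                            do.call(rbind, tab), row.names = NULL)
  stage("mantel", NULL)

  geoPcs <- leadingPcnm(geoD, k = max(8L, pcsPerMatrix))
  candidates <- lapply(varMats, leadingPcnm, k = pcsPerMatrix)
  dbrda1 <- dbrda2 <- NULL
  if (length(candidates)) {
    cand1 <- c(candidates,
               list(Distance = geoPcs[, seq_len(pcsPerMatrix), drop = FALSE]))
    dbrda1 <- forwardSelectDbrda(aM, cand1, nPerm = nPerm, seed = seed)
    cond <- selectConditionalPcs(aM, geoPcs, alpha = alpha, nPerm = nPerm,
                                 seed = seed)
    if (!ncol(cond)) cond <- geoPcs[, 1, drop = FALSE]
    dbrda2 <- forwardSelectDbrda(aM, candidates, conditional = cond,
                                 nPerm = nPerm, seed = seed)
  }
  stage("dbrda", NULL)

  type1Report <- NULL
  if (isTRUE(type1)) {
    if (is.null(type1Config)) stop("type1Config is required for the suite")
    if (is.null(landscape) || !length(landscape@habitat))
      stop("a landscape with a habitat raster is required for the suite")
    pl <- placeLocations(landscape@habitat, type1Config@nLocations,
                         focalPoints = xy,
                         jitterRadius = type1Config@jitterRadius,
                         seed = seed)
    type1Report <- runType1Suite(type1Config, varMats, geoD, pl$points,
                                 pl$focalIdx, nSims = type1Sims,
                                 nPerm = min(nPerm, 199L), seed = seed)
    mantelTable$type1Count <- NA_integer_
    idx <- match(names(type1Report@partialCounts), mantelTable$variable)
    mantelTable$type1Count[idx] <- type1Report@partialCounts
    stage("type1", NULL)
  }

  res <- list(genotypes = g, kinshipMatrix = k, kinshipCalls = calls,
              retained = retained, pruned = gP, roussetA = aM, neiD = dM,
              amova = am, geoD = geoD, varMatrices = varMats,
              mantelTable = mantelTable, dbrda1 = dbrda1, dbrda2 = dbrda2,
              type1 = type1Report, log = log)
  if (!is.null(outDir)) .writeArtifacts(res, outDir)
  res
}

.writeArtifacts <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeGenotypeTsv(res$pruned, file.path(outDir, "genotypes_pruned.tsv"))
  writeFilterReportJson(res$genotypes, file.path(outDir, "filter_report.json"))
  write.csv(res$kinshipCalls, file.path(outDir, "kinship_calls.csv"),
            row.names = FALSE)
  writePairwiseCsv(res$roussetA, file.path(outDir, "rousset_a.csv"))
  writePairwiseCsv(res$neiD, file.path(outDir, "nei_d.csv"))
  write.csv(res$mantelTable, file.path(outDir, "mantel_table.csv"),
            row.names = FALSE)
  am <- res$amova
  jsonlite::write_json(list(ssAmong = am@ssAmong, ssWithin = am@ssWithin,
                            etaSq = am@etaSq, p = am@p),
                       file.path(outDir, "amova.json"),
                       auto_unbox = TRUE, digits = NA)
  dumpDbrda <- function(d, path) {
    if (is.null(d)) return()
    jsonlite::write_json(list(order = d$order, adjR2 = d$model@adjR2,
                              terms = d$model@terms,
                              vif = as.list(d$model@vif)),
                         path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  dumpDbrda(res$dbrda1, file.path(outDir, "dbrda1.json"))
  dumpDbrda(res$dbrda2, file.path(outDir, "dbrda2.json"))
  if (!is.null(res$type1))
    writeType1Json(res$type1, file.path(outDir, "type1_report.json"))
  writeLines(vapply(res$log, function(rec)
    jsonlite::toJSON(rec, auto_unbox = TRUE), character(1)),
    file.path(outDir, "log.jsonl"))
  invisible(outDir)
}
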