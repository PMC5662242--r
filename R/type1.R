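#' First spatial eigenvector columns of a pairwise matrix
#'
#' Convenience used to build dbRDA designs: PCNM of the matrix, returning
#' the first `k` eigenvectors (fewer if fewer are positive).
#'
#' @param D a [PairwiseMatrix-class]
#' @param k number of leading eigenvectors (default 2)
#' @export
leadingPcnm <- function(D, k = 2L) {
  b <- pcnmBasis(D)
  b@vectors[, seq_len(min(k, ncol(b@vectors))), drop = FALSE]
}

#' Select conditioning spatial eigenvectors by marginal significance
#'
#' Fits a dbRDA of all supplied geographic eigenvectors (each its own term)
#' on the response distances, adjusts the marginal permutation p-values by
#' Benjamini-Hochberg, and returns the eigenvectors significant at `alpha`
#' — the conditional matrix of the geography-partialled model.
#'
#' @param responseD response distance [PairwiseMatrix-class]
#' @param geoPcs matrix of geographic spatial eigenvectors
#' @param alpha significance level after BH adjustment (default 0.05)
#' @param nPerm permutations (default 999)
#' @param seed optional RNG seed
#' @export
selectConditionalPcs <- function(responseD, geoPcs, alpha = 0.05,
                                 nPerm = 999L, seed = NULL) {
  terms <- lapply(seq_len(ncol(geoPcs)), function(i) geoPcs[, i, drop = FALSE])
  names(terms) <- paste0("geoPC", seq_len(ncol(geoPcs)))
  fit <- fitDbrda(responseD, terms, nPerm = nPerm, seed = seed)
  keep <- which(fit@terms$pBH < alpha)
  geoPcs[, keep, drop = FALSE]
}

#' Simulation-based Type-I-error screen for landscape models
#'
#' Runs `nSims` IBD-only forward simulations over a fixed location set (the
#' simulations contain no landscape effect whatsoever), samples the focal
#' locations, and refits the empirical statistical models on every
#' simulated dataset: a Mantel test of genetic distance (Rousset's a)
#' against log geographic distance records the realized IBD strength, each
#' landscape variable is retested by partial Mantel (variable | distance),
#' and the geography-conditioned dbRDA is refitted with the same term
#' structure as the empirical model. Any significance observed is spurious
#' by construction; a variable whose count of significant simulations
#' strictly exceeds `alpha * nSims` is flagged as carrying an elevated
#' Type-I-error risk (untestable with this sampling design).
#'
#' The landscape matrices are computed once from the real (or fixture)
#' geometry and reused across simulations — only the genetic data are
#' simulated.
#'
#' @param config a [SimulationConfig-class] (its seed is ignored; `seed`
#'   governs the suite)
#' @param landscapeMatrices named list of [PairwiseMatrix-class] over the
#'   focal individuals, in focal-point order
#' @param geoD geographic distance [PairwiseMatrix-class] over the focal
#'   individuals (metres)
#' @param locations all simulated locations (n x 2)
#' @param focalIdx indices of the focal locations
#' @param nSims number of simulations (default 100)
#' @param alpha per-test significance level (default 0.05)
#' @param nPerm permutations per Mantel/dbRDA test (default 99 within the
#'   suite)
#' @param conditional optional conditioning matrix for the dbRDA refits;
#'   derived from `geoD` ([selectConditionalPcs()] needs an empirical
#'   response, so the default uses the first four geographic eigenvectors)
#' @param dbrdaTerms optional named list of term matrices; default: first
#'   two spatial eigenvectors of every landscape matrix
#' @param seed master seed of the suite
#' @return a [Type1Report-class]
#' @export
runType1Suite <- function(config, landscapeMatrices, geoD, locations,
                          focalIdx, nSims = 100L, alpha = 0.05,
                          nPerm = 99L, conditional = NULL,
                          dbrdaTerms = NULL, seed = 1L) {
  vars <- names(landscapeMatrices)
  if (nSims == 0L) {
    return(new("Type1Report",
               partialCounts = setNames(integer(0), character(0)),
               dbrdaCounts = setNames(integer(0), character(0)),
               partialFlags = setNames(logical(0), character(0)),
               dbrdaFlags = setNames(logical(0), character(0)),
               ibdR = numeric(0), ibdP = numeric(0), nSims = 0L,
               alpha = alpha))
  }
  nf <- length(focalIdx)
  labs <- paste0("sim", focalIdx)
  relabel <- function(pm) {
    m <- as.matrix(pm)
    stopifnot(nrow(m) == nf)
    dimnames(m) <- list(labs, labs)
    PairwiseMatrix(m, kind = pairKind(pm))
  }
  landscapeMatrices <- lapply(landscapeMatrices, relabel)
  geoD <- relabel(geoD)
  logGeo <- PairwiseMatrix(log(as.matrix(geoD) + 1), kind = "geographic")
  if (is.null(dbrdaTerms))
    dbrdaTerms <- lapply(landscapeMatrices, leadingPcnm, k = 2L)
  if (is.null(conditional))
    conditional <- leadingPcnm(geoD, k = 4L)
  partialCounts <- setNames(integer(length(vars)), vars)
  dbrdaCounts <- setNames(integer(length(dbrdaTerms)), names(dbrdaTerms))
  ibdR <- ibdP <- numeric(nSims)
  for (s in seq_len(nSims)) {
    simSeed <- as.integer((as.numeric(seed) * 1000 + s * 7919) %% 2147483647)
    cfg <- config
    cfg@seed <- simSeed
    pop <- tryCatch(runSimulation(cfg, locations), error = function(e)
      stop("simulation ", s, " failed: ", conditionMessage(e)))
    gm <- samplePopulation(pop, focalIdx)
    aM <- roussetA(gm)
    ibd <- mantelTest(aM, logGeo, nPerm = nPerm, seed = simSeed + 1L)
    ibdR[s] <- ibd@r; ibdP[s] <- ibd@p
    for (v in vars) {
      pm <- partialMantelTest(aM, landscapeMatrices[[v]], logGeo,
                              nPerm = nPerm, seed = simSeed + 2L)
      if (pm@p < alpha) partialCounts[v] <- partialCounts[v] + 1L
    }
    fit <- fitDbrda(aM, dbrdaTerms, conditional, nPerm = nPerm,
                    seed = simSeed + 3L)
    sig <- fit@terms$term[fit@terms$p < alpha]
    dbrdaCounts[sig] <- dbrdaCounts[sig] + 1L
  }
  thr <- alpha * nSims
  new("Type1Report", partialCounts = partialCounts,
      dbrdaCounts = dbrdaCounts,
      partialFlags = partialCounts > thr,    # strictly greater
      dbrdaFlags = dbrdaCounts > thr,
      ibdR = ibdR, ibdP = ibdP, nSims = as.integer(nSims), alpha = alpha)
}

setMethod("show", "Type1Report", function(object) {
  cat(sprintf("Type-I-error screen: %d simulations, alpha %.2f\n",
              object@nSims, object@alpha))
  if (length(object@ibdR))
    cat(sprintf("  simulated IBD: mean r = %.3f (sd %.3f); %d/%d P < 0.05\n",
                mean(object@ibdR), sd(object@ibdR),
                sum(object@ibdP < 0.05), object@nSims))
  for (v in names(object@partialCounts))
    cat(sprintf("  partial Mantel %-20s %3d/%d significant%s\n", v,
                object@partialCounts[v], object@nSims,
                if (object@partialFlags[v]) "  [INFLATED]" else ""))
  for (v in names(object@dbrdaCounts))
    cat(sprintf("  dbRDA term    %-20s %3d/%d significant%s\n", v,
                object@dbrdaCounts[v], object@nSims,
                if (object@dbrdaFlags[v]) "  [INFLATED]" else ""))
})

#' Check simulated IBD strength against the empirical value
#'
#' TRUE when the mean simulated Mantel correlation lies within `tolerance`
#' of `empiricalR` and at least `minSigFraction` of the simulations were
#' individually significant at 0.05.
#'
#' @param report a [Type1Report-class]
#' @param empiricalR empirical Mantel correlation of genetic distance with
#'   log geographic distance
#' @param tolerance allowed deviation of the mean (default 0.02)
#' @param minSigFraction required fraction of significant simulations
#'   (default 1, i.e. all)
#' @export
verifyIbdMatch <- function(report, empiricalR, tolerance = 0.02,
                           minSigFraction = 1) {
  if (!length(report@ibdR)) return(FALSE)
  meanOk <- abs(mean(report@ibdR) - empiricalR) <= tolerance
  sigOk <- mean(report@ibdP < 0.05) >= minSigFraction
  meanOk && sigOk
}

#' Serialise a Type1Report as JSON
#' @param report a [Type1Report-class]
#' @param path output file
#' @export
writeType1Json <- function(report, path) {
  jsonlite::write_json(list(
    nSims = report@nSims, alpha = report@alpha,
    type1_count = as.list(report@partialCounts),
    dbrda_count = as.list(report@dbrdaCounts),
    inflated = as.list(report@partialFlags),
    dbrda_inflated = as.list(report@dbrdaFlags),
    ibd_r = report@ibdR, ibd_p = report@ibdP),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
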