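#' @import methods
#' @importFrom stats cor dist lm.fit median na.omit optim p.adjust pnorm quantile rbinom resid rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowRanges
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' GenotypeMatrix: individuals x biallelic SNP loci
#'
#' An S4 container for filtered biallelic SNP genotypes, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are loci (with
#' genomic coordinates and ref/alt alleles held in `rowRanges`), columns are
#' individuals (with site membership and projected x/y coordinates in metres
#' held in `colData`). The single assay `"calls"` stores alternate-allele
#' dosages 0/1/2 with `NA` as the missing-call sentinel; every downstream
#' statistic branches on `NA` explicitly.
#'
#' Invariants enforced by the validity method: calls are in `{0, 1, 2, NA}`,
#' individual identifiers are unique, every individual maps to exactly one
#' site, and loci are sorted by (scaffold, position).
#'
#' @seealso [GenotypeMatrix()] for construction, [dosageMatrix()],
#'   [filterIndividuals()], [filterLoci()], [thinByDistance()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (!("calls" %in% names(a)))
    return("assay 'calls' is required")
  calls <- a[["calls"]]
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "calls must be 0, 1, 2 or NA (missing)")
  cd <- SummarizedExperiment::colData(object)
  if (!("site" %in% colnames(cd)))
    msg <- c(msg, "colData must contain a 'site' column")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids must be unique")
  if (nrow(object) > 1) {
    rr <- SummarizedExperiment::rowRanges(object)
    o <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    if (!identical(o, seq_len(nrow(object))))
      msg <- c(msg, "loci must be sorted by (scaffold, position)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' PairwiseMatrix: symmetric individual- or site-level matrix
#'
#' Symmetric real matrix over a common label set, used for genetic distance
#' (Rousset's a, Nei's D), kinship, geographic distance, network isolation
#' and barrier matrices. The `kind` tag records what the values are; all
#' matrix statistics ([mantelTest()], [fitDbrda()], [amova()]) consume this
#' class.
#'
#' @slot values square symmetric numeric matrix with label dimnames
#' @slot kind one of `"genetic-distance"`, `"kinship"`, `"geographic"`,
#'   `"isolation"`, `"barrier"`, `"generic"`
#' @export
setClass("PairwiseMatrix",
         representation(values = "matrix", kind = "character"))

.validPairwiseMatrix <- function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("matrix must carry identical row/column labels")
  fin <- is.finite(v) & is.finite(t(v))
  if (any(abs(v[fin] - t(v)[fin]) > 1e-8 * (1 + max(abs(v[fin])))))
    return("matrix must be symmetric")
  TRUE
}
setValidity("PairwiseMatrix", .validPairwiseMatrix)

#' FilterReport: accounting for one filtering rule
#'
#' @slot rule filter rule name
#' @slot axis `"individual"` or `"locus"`
#' @slot nRemoved number of items removed
#' @slot nRetained number of items retained
#' @slot params list of the thresholds used
#' @export
setClass("FilterReport",
         representation(rule = "character", axis = "character",
                        nRemoved = "integer", nRetained = "integer",
                        params = "list"))

#' MantelResult: simple or partial Mantel test outcome
#' @slot r matrix correlation over off-diagonal entries
#' @slot p one-tailed (greater) permutation p-value, plus-one corrected
#' @slot nPerm number of permutations
#' @slot tail alternative used (always `"greater"`)
#' @slot kind `"mantel"` or `"partial-mantel"`
#' @export
setClass("MantelResult",
         representation(r = "numeric", p = "numeric", nPerm = "integer",
                        tail = "character", kind = "character"))

#' AmovaResult: one-level AMOVA from squared pairwise distances
#' @slot ssAmong,ssWithin,ssTotal sums of squares
#' @slot dfAmong,dfWithin degrees of freedom
#' @slot sigmaAmong,sigmaWithin variance components
#' @slot etaSq proportion of total SS among groups (effect size)
#' @slot statistic observed pseudo-F
#' @slot p permutation p-value (group labels permuted, plus-one corrected)
#' @slot nPerm number of permutations
#' @export
setClass("AmovaResult",
         representation(ssAmong = "numeric", ssWithin = "numeric",
                        ssTotal = "numeric", dfAmong = "numeric",
                        dfWithin = "numeric", sigmaAmong = "numeric",
                        sigmaWithin = "numeric", etaSq = "numeric",
                        statistic = "numeric", p = "numeric",
                        nPerm = "integer"))

#' PcnmBasis: spatial eigenvectors of a truncated distance matrix
#' @slot vectors n x k orthonormal eigenvectors (positive eigenvalues only)
#' @slot values the k positive eigenvalues, decreasing
#' @slot truncation truncation distance (longest minimum-spanning-tree edge)
#' @export
setClass("PcnmBasis",
         representation(vectors = "matrix", values = "numeric",
                        truncation = "numeric"))

#' OrdinationModel: fitted distance-based redundancy analysis
#'
#' Holds the principal-coordinates embedding of the response distance matrix,
#' the inertia decomposition (conditional / constrained / unconstrained), the
#' adjusted R-squared, and per-term marginal statistics (eta-squared,
#' pseudo-F, raw and Benjamini-Hochberg-adjusted permutation p-values) plus
#' variance inflation factors of the explanatory design after conditioning.
#'
#' @export
setClass("OrdinationModel",
         representation(totalInertia = "numeric",
                        conditionalInertia = "numeric",
                        constrainedInertia = "numeric",
                        unconstrainedInertia = "numeric",
                        r2 = "numeric", adjR2 = "numeric",
                        terms = "data.frame", vif = "numeric",
                        nPerm = "integer", n = "integer"))

.validOrdinationModel <- function(object) {
  tot <- object@conditionalInertia + object@constrainedInertia +
    object@unconstrainedInertia
  if (abs(tot - object@totalInertia) > 1e-8 * (1 + object@totalInertia))
    return("inertia decomposition must sum to total inertia")
  TRUE
}
setValidity("OrdinationModel", .validOrdinationModel)

#' LandscapeModel: urban geography for isolation metrics and simulation
#'
#' @slot ports n x 2 matrix of port/shipping-terminal coordinates (m)
#' @slot rivers list of polylines (each an m x 2 coordinate matrix)
#' @slot highways list of polylines; nominal total carriageway width in
#'   `highwayWidth` (default 30 m)
#' @slot railways optional list of polylines (same operator as highways)
#' @slot highwayWidth numeric, metres
#' @slot habitat list with `x`, `y` (cell-centre coordinates) and `values`
#'   (matrix, length(x) rows) describing a habitat-index raster, or empty
#' @slot extent numeric xmin/xmax/ymin/ymax bounding box
#' @export
setClass("LandscapeModel",
         representation(ports = "matrix", rivers = "list",
                        highways = "list", railways = "list",
                        highwayWidth = "numeric", habitat = "list",
                        extent = "numeric"))

#' SimulationConfig: parameters of the IBD-only forward simulation
#'
#' Defaults mirror the study conditions of the Type-I-error null: 1500
#' occupied locations including 116 focal (sampled) points jittered by up to
#' 250 m, 1847 biallelic loci initialised at maximum diversity, 100
#' non-overlapping generations, negative-exponential dispersal with median
#' realized dispersal under 500 m, and habitat-density weights 1:3:5 for the
#' three habitat-index strata.
#'
#' @export
setClass("SimulationConfig",
         representation(nLocations = "integer", nFocal = "integer",
                        jitterRadius = "numeric", nLoci = "integer",
                        generations = "integer", dispersalScale = "numeric",
                        densityWeights = "numeric", seed = "integer"))

.validSimulationConfig <- function(object) {
  msg <- character()
  if (object@nLocations < 1L || object@nLoci < 1L || object@generations < 0L)
    msg <- c(msg, "counts must be positive")
  if (object@nFocal > object@nLocations)
    msg <- c(msg, "nFocal cannot exceed nLocations")
  if (any(object@densityWeights <= 0))
    msg <- c(msg, "density weights must be positive")
  if (object@dispersalScale <= 0)
    msg <- c(msg, "dispersal scale must be positive")
  # focal jitter must stay below the median of the dispersal kernel
  if (is.finite(object@dispersalScale) &&
      object@jitterRadius >= object@dispersalScale * log(2))
    msg <- c(msg, "jitter radius must be below the kernel median dispersal")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' SimulatedPopulation: state of a finished forward simulation
#'
#' @slot locations fixed n x 2 occupied locations (one individual each)
#' @slot maternal,paternal n x L 0/1 allele matrices of the final generation
#' @slot parentMaternal,parentPaternal allele matrices of the parent
#'   generation (for Mendelian-consistency checks)
#' @slot parentage data.frame (offspring, mother, father) for the final
#'   generation
#' @slot dispersal realized mother-to-offspring distances pooled over
#'   generations (m)
#' @slot hetTrajectory mean expected heterozygosity per generation
#' @slot config the [SimulationConfig-class] that produced the run
#' @export
setClass("SimulatedPopulation",
         representation(locations = "matrix", maternal = "matrix",
                        paternal = "matrix", parentMaternal = "matrix",
                        parentPaternal = "matrix", parentage = "data.frame",
                        dispersal = "numeric", hetTrajectory = "numeric",
                        config = "SimulationConfig"))

#' Type1Report: outcome of the simulation-based Type-I-error screen
#'
#' @slot partialCounts named integer: per landscape variable, number of
#'   IBD-only simulations whose partial Mantel test (variable | geographic
#'   distance) was significant at `alpha`
#' @slot dbrdaCounts named integer: per dbRDA term, number of simulations
#'   with a significant marginal permutation test
#' @slot partialFlags,dbrdaFlags inflated if count strictly exceeds
#'   `alpha * nSims`
#' @slot ibdR,ibdP per-simulation Mantel correlation (genetic distance vs
#'   log geographic distance) and its p-value
#' @export
setClass("Type1Report",
         representation(partialCounts = "integer", dbrdaCounts = "integer",
                        partialFlags = "logical", dbrdaFlags = "logical",
                        ibdR = "numeric", ibdP = "numeric",
                        nSims = "integer", alpha = "numeric"))
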