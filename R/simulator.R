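#' Construct a SimulationConfig
#'
#' Defaults are the study conditions of the Type-I-error null model: 1500
#' occupied locations, 116 focal sampling points jittered by up to 250 m,
#' 1847 biallelic loci initialised at maximum diversity (the count that
#' matches 3694 effective alleles), 100 non-overlapping generations, and
#' negative-exponential dispersal whose realized median is well under
#' 500 m. Density weights 1:3:5 govern location placement across the three
#' habitat-index strata (0-2, 2-4, 4-6).
#'
#' @param nLocations number of occupied locations (default 1500)
#' @param nFocal number of focal (sampled) locations (default 116)
#' @param jitterRadius focal jitter radius, m (default 250; must stay below
#'   the median dispersal scale)
#' @param nLoci biallelic loci (default 1847)
#' @param generations discrete generations (default 100)
#' @param dispersalScale scale b of the exp(-d/b) kernel, m (default 500:
#'   kernel median b log 2 of about 347 m, most dispersal within 500 m)
#' @param densityWeights relative density of the three habitat strata
#' @param seed RNG seed for the run
#' @export
simulationConfig <- function(nLocations = 1500L, nFocal = 116L,
                             jitterRadius = 250, nLoci = 1847L,
                             generations = 100L, dispersalScale = 500,
                             densityWeights = c(1, 3, 5), seed = 1L) {
  new("SimulationConfig", nLocations = as.integer(nLocations),
      nFocal = as.integer(nFocal), jitterRadius = jitterRadius,
      nLoci = as.integer(nLoci), generations = as.integer(generations),
      dispersalScale = dispersalScale, densityWeights = densityWeights,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d locations (%d focal, jitter %g m), %d loci, %d generations, dispersal scale %g m, seed %d\n",
    object@nLocations, object@nFocal, object@jitterRadius, object@nLoci,
    object@generations, object@dispersalScale, object@seed))
})

#' Generate a reproducible synthetic urban landscape
#'
#' Emulates a port-city geography for tests and simulations: shipping
#' terminals, river polylines, a highway grid and a stratified
#' habitat-index raster with values spanning the three density strata
#' (0-2, 2-4, 4-6). In `"confounded"` mode all ports sit on the western
#' edge, so port isolation increases with the x coordinate (spatially
#' confounded with geography); in `"unconfounded"` mode ports are spread on
#' a symmetric internal grid, making isolation essentially orthogonal to
#' position.
#'
#' @param nPorts number of shipping terminals (default 5)
#' @param extent c(xmin, xmax, ymin, ymax), metres (default 30 x 30 km)
#' @param mode `"unconfounded"` or `"confounded"`
#' @param cellSize habitat raster cell size, m (default 1000)
#' @param seed RNG seed
#' @return a [LandscapeModel-class]
#' @export
generateLandscape <- function(nPorts = 5, extent = c(0, 30000, 0, 30000),
                              mode = c("unconfounded", "confounded"),
                              cellSize = 1000, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (mode == "confounded") {
    ports <- cbind(extent[1] + runif(nPorts, 0, 0.02 * w),
                   extent[3] + (seq_len(nPorts) - 0.5) / nPorts * h)
  } else {
    k <- ceiling(sqrt(nPorts))
    gx <- extent[1] + (seq_len(k) - 0.5) / k * w
    gy <- extent[3] + (seq_len(k) - 0.5) / k * h
    grid <- as.matrix(expand.grid(gx, gy))
    # spread the picks symmetrically over the grid
    pick <- round(seq(1, nrow(grid), length.out = nPorts))
    ports <- grid[pick, , drop = FALSE]
  }
  wiggly <- function(y0, n = 20) {
    x <- seq(extent[1], extent[2], length.out = n)
    cbind(x, y0 + cumsum(rnorm(n, 0, h / 60)))
  }
  rivers <- list(wiggly(extent[3] + 0.35 * h), wiggly(extent[3] + 0.7 * h))
  highways <- c(
    lapply(c(0.25, 0.5, 0.75), function(f)
      cbind(c(extent[1], extent[2]), rep(extent[3] + f * h, 2))),
    lapply(c(0.25, 0.5, 0.75), function(f)
      cbind(rep(extent[1] + f * w, 2), c(extent[3], extent[4]))))
  xs <- seq(extent[1] + cellSize / 2, extent[2], by = cellSize)
  ys <- seq(extent[3] + cellSize / 2, extent[4], by = cellSize)
  # smooth diagonal habitat gradient plus noise, clamped into [0, 6]
  vals <- outer(xs, ys, function(x, y)
    3 + 2.5 * sin(2 * pi * x / w) * cos(2 * pi * y / h))
  vals <- vals + matrix(rnorm(length(vals), 0, 0.5), nrow(vals))
  vals[vals < 0] <- 0
  vals[vals > 6] <- 6
  LandscapeModel(ports = ports, rivers = rivers, highways = highways,
                 habitat = list(x = xs, y = ys, values = vals),
                 extent = extent)
}

#' Place individual locations by habitat-weighted sampling
#'
#' Focal points are jittered uniformly within a disc of `jitterRadius`
#' (every individual moves, none further than the radius). The remaining
#' `nLocations - nrow(focalPoints)` locations are drawn from the habitat
#' raster cells with probability proportional to the stratum weight of the
#' cell value (strata 0-2 / 2-4 / 4-6 at weights 1:3:5 by default) and
#' placed uniformly within the chosen cell. Duplicate coordinates are
#' redrawn.
#'
#' @param raster habitat raster list(x, y, values)
#' @param nLocations total number of locations
#' @param focalPoints optional n x 2 matrix of focal coordinates
#' @param jitterRadius metres (default 250)
#' @param weights stratum weights (default c(1, 3, 5))
#' @param seed RNG seed
#' @return list with `points` (nLocations x 2), `focalIdx` (indices of the
#'   jittered focal points, first rows)
#' @export
placeLocations <- function(raster, nLocations, focalPoints = NULL,
                           jitterRadius = 250, weights = c(1, 3, 5),
                           seed = 1L) {
  set.seed(seed)
  nFocal <- if (is.null(focalPoints)) 0L else nrow(focalPoints)
  if (nLocations < nFocal) stop("nLocations is less than the number of focal points")
  out <- matrix(NA_real_, nLocations, 2)
  if (nFocal) {
    rr <- jitterRadius * sqrt(runif(nFocal))
    th <- runif(nFocal, 0, 2 * pi)
    out[seq_len(nFocal), ] <- cbind(focalPoints[, 1] + rr * cos(th),
                                    focalPoints[, 2] + rr * sin(th))
  }
  nFree <- nLocations - nFocal
  if (nFree > 0) {
    cell <- raster$x[2] - raster$x[1]
    grid <- expand.grid(ix = seq_along(raster$x), iy = seq_along(raster$y))
    stratum <- findInterval(as.vector(raster$values), c(2, 4)) + 1L
    wCell <- weights[stratum]
    pick <- sample.int(nrow(grid), nFree, replace = TRUE, prob = wCell)
    out[nFocal + seq_len(nFree), ] <-
      cbind(raster$x[grid$ix[pick]] + runif(nFree, -cell / 2, cell / 2),
            raster$y[grid$iy[pick]] + runif(nFree, -cell / 2, cell / 2))
  }
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup, ] <- out[dup, , drop = FALSE] + runif(2 * length(dup), -0.5, 0.5)
  }
  list(points = out, focalIdx = seq_len(nFocal))
}

#' Run the IBD-only spatially explicit forward simulation
#'
#' A fixed set of locations each holds exactly one individual. Generations
#' are discrete and non-overlapping (every adult dies, every location is
#' refilled — the high-recruitment / high-mortality regime): the offspring
#' filling a location draws its mother from all locations with probability
#' proportional to `exp(-d / b)` of the distance to that location, and its
#' father (excluding the mother, no selfing) with probability proportional
#' to `exp(-d_from_mother / b)`. Each parent transmits one allele per locus
#' uniformly at random; there is no mutation and no selection, so the only
#' genetic structure that can arise is isolation by distance plus drift.
#' Initial genotypes are independent Bernoulli(0.5) alleles (maximum
#' diversity). `b = Inf` gives panmixia.
#'
#' @param config a [SimulationConfig-class]
#' @param locations n x 2 matrix of occupied locations (defaults to
#'   uniform random placement over the unit 30 km square)
#' @return a [SimulatedPopulation-class]
#' @export
runSimulation <- function(config, locations = NULL) {
  set.seed(config@seed)
  n <- config@nLocations
  if (is.null(locations)) {
    locations <- cbind(runif(n, 0, 30000), runif(n, 0, 30000))
  }
  stopifnot(nrow(locations) == n)
  L <- config@nLoci
  b <- config@dispersalScale
  D <- as.matrix(dist(locations))
  W <- if (is.infinite(b)) matrix(1, n, n) else exp(-D / b)
  if (any(!is.finite(W))) stop("non-finite dispersal kernel weights")
  cumW <- apply(W, 2, cumsum)            # column i: kernel into location i
  totW <- cumW[n, ]
  mat <- matrix(rbinom(n * L, 1L, 0.5), n, L)
  pat <- matrix(rbinom(n * L, 1L, 0.5), n, L)
  het <- numeric(config@generations + 1L)
  hetOf <- function(m1, m2) {
    p <- (colSums(m1) + colSums(m2)) / (2 * n)
    mean(2 * p * (1 - p))
  }
  het[1] <- hetOf(mat, pat)
  dispersal <- numeric(0)
  mothers <- fathers <- integer(n)
  pm <- mat; pp <- pat
  for (gen in seq_len(config@generations)) {
    u <- runif(n) * totW
    for (i in seq_len(n)) {
      mothers[i] <- findInterval(u[i], cumW[, i]) + 1L
      # father by dispersal from the mother's location, no selfing
      m <- mothers[i]
      wf <- W[, m]; wf[m] <- 0
      fathers[i] <- findInterval(runif(1) * sum(wf), cumsum(wf)) + 1L
    }
    pickM <- matrix(runif(n * L) < 0.5, n, L)
    pickP <- matrix(runif(n * L) < 0.5, n, L)
    pm <- mat; pp <- pat
    gM <- ifelse(pickM, pm[mothers, ], pp[mothers, ])
    gP <- ifelse(pickP, pm[fathers, ], pp[fathers, ])
    mat <- gM; pat <- gP
    dispersal <- c(dispersal, D[cbind(seq_len(n), mothers)])
    het[gen + 1L] <- hetOf(mat, pat)
  }
  new("SimulatedPopulation", locations = locations, maternal = mat,
      paternal = pat, parentMaternal = pm, parentPaternal = pp,
      parentage = data.frame(offspring = seq_len(n), mother = mothers,
                             father = fathers),
      dispersal = dispersal, hetTrajectory = het, config = config)
}

#' Median realized dispersal distance of a finished run
#' @param pop a [SimulatedPopulation-class]
#' @export
medianDispersal <- function(pop) {
  if (!length(pop@dispersal)) return(NA_real_)
  median(pop@dispersal)
}

setMethod("show", "SimulatedPopulation", function(object) {
  cat(sprintf(
    "SimulatedPopulation: %d locations x %d loci after %d generations; median dispersal %.0f m; final He %.3f\n",
    nrow(object@locations), ncol(object@maternal),
    object@config@generations, medianDispersal(object),
    object@hetTrajectory[length(object@hetTrajectory)]))
})

#' Sample the simulated population at focal locations
#'
#' Extracts the final-generation occupants of the given location indices as
#' a [GenotypeMatrix-class] of alternate-allele dosages. Loci are assigned
#' synthetic coordinates (one scaffold, 250 kbp spacing).
#'
#' @param pop a [SimulatedPopulation-class]
#' @param focalIdx indices into the simulation's location set
#' @param sites optional site labels per focal individual (default one
#'   site per individual is not useful, so a single site `"sim"`)
#' @export
samplePopulation <- function(pop, focalIdx, sites = NULL) {
  if (any(focalIdx < 1 | focalIdx > nrow(pop@locations)))
    stop("focal index outside the simulated location set")
  dos <- pop@maternal[focalIdx, , drop = FALSE] +
    pop@paternal[focalIdx, , drop = FALSE]
  L <- ncol(dos)
  ids <- paste0("sim", focalIdx)
  if (is.null(sites)) sites <- rep("sim", length(focalIdx))
  GenotypeMatrix(
    calls = dos,
    loci = data.frame(scaffold = "simscaf", position = (seq_len(L) - 1) * 250000L),
    samples = data.frame(id = ids, site = sites,
                         x = pop@locations[focalIdx, 1],
                         y = pop@locations[focalIdx, 2]))
}

#' Generate a pedigreed genotype fixture with known sibships
#'
#' Draws unrelated parents from Hardy-Weinberg proportions at the supplied
#' allele frequencies (an outbred reference pool), produces full-sib
#' families (both parents shared), half-sib families (mother shared,
#' fathers distinct) and unrelated singletons, then sprinkles missing calls
#' at `missingRate`. The truth table records family membership and parents
#' so that true pairwise relationships can be reconstructed exactly.
#'
#' @param nFamilies number of full-sib families
#' @param familySizes integer vector (recycled) of offspring per family
#' @param nUnrelated number of unrelated singletons
#' @param nLoci number of biallelic loci
#' @param freqs optional per-locus alternate-allele frequencies (default
#'   Uniform(0.1, 0.9) draws)
#' @param missingRate per-call missing probability (default 0)
#' @param nHalfSibFamilies number of half-sib families (default 0)
#' @param seed RNG seed
#' @return list with `genotypes` ([GenotypeMatrix-class]), `truth`
#'   (per-individual family/type/parents), `parents` (each parent's two
#'   allele rows, for Mendelian-consistency checks) and `freqs`
#' @export
generatePedigreeFixture <- function(nFamilies, familySizes = 2L,
                                    nUnrelated = 0L, nLoci = 300L,
                                    freqs = NULL, missingRate = 0,
                                    nHalfSibFamilies = 0L, seed = 1L) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(nLoci, 0.1, 0.9)
  stopifnot(length(freqs) == nLoci, all(freqs >= 0), all(freqs <= 1))
  drawParent <- function() rbind(rbinom(nLoci, 1L, freqs),
                                 rbinom(nLoci, 1L, freqs))
  child <- function(mo, fa) {
    mo[cbind(sample(1:2, nLoci, TRUE), seq_len(nLoci))] +
      fa[cbind(sample(1:2, nLoci, TRUE), seq_len(nLoci))]
  }
  sizes <- rep_len(familySizes, nFamilies + nHalfSibFamilies)
  rows <- list(); truth <- list(); parents <- list(); idn <- 0L
  addInd <- function(g, fam, type, mother, father) {
    idn <<- idn + 1L
    id <- sprintf("ind%03d", idn)
    rows[[id]] <<- g
    truth[[id]] <<- data.frame(id = id, family = fam, type = type,
                               mother = mother, father = father)
  }
  newParent <- function(id) {
    p <- drawParent()
    parents[[id]] <<- p
    p
  }
  for (f in seq_len(nFamilies)) {
    mo <- newParent(paste0("FS", f, "m"))
    fa <- newParent(paste0("FS", f, "f"))
    for (k in seq_len(sizes[f]))
      addInd(child(mo, fa), paste0("FS", f), "full-sib-family",
             paste0("FS", f, "m"), paste0("FS", f, "f"))
  }
  for (f in seq_len(nHalfSibFamilies)) {
    mo <- newParent(paste0("HS", f, "m"))
    for (k in seq_len(sizes[nFamilies + f]))
      addInd(child(mo, newParent(paste0("HS", f, "f", k))),
             paste0("HS", f), "half-sib-family",
             paste0("HS", f, "m"), paste0("HS", f, "f", k))
  }
  for (u in seq_len(nUnrelated))
    addInd(child(newParent(paste0("U", u, "m")),
                 newParent(paste0("U", u, "f"))),
           paste0("U", u), "unrelated",
           paste0("U", u, "m"), paste0("U", u, "f"))
  calls <- do.call(rbind, rows)
  if (missingRate > 0)
    calls[matrix(runif(length(calls)) < missingRate, nrow(calls))] <- NA
  gm <- GenotypeMatrix(
    calls = calls,
    loci = data.frame(scaffold = "pedscaf",
                      position = (seq_len(nLoci) - 1) * 250000L),
    samples = data.frame(id = names(rows), site = "S1"))
  list(genotypes = gm, truth = do.call(rbind, unname(truth)),
       parents = parents, freqs = freqs)
}
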