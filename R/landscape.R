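#' Construct a LandscapeModel
#'
#' @param ports n x 2 matrix (or data.frame) of port coordinates, metres
#' @param rivers,highways,railways lists of polylines, each an m x 2
#'   coordinate matrix
#' @param highwayWidth nominal total carriageway width, metres (default 30)
#' @param habitat optional list with `x`, `y` (cell-centre coordinate
#'   vectors) and `values` (matrix `length(x)` x `length(y)`) describing a
#'   habitat-index raster
#' @param extent optional c(xmin, xmax, ymin, ymax); derived from the
#'   geometry when missing
#' @export
LandscapeModel <- function(ports = matrix(numeric(0), 0, 2), rivers = list(),
                           highways = list(), railways = list(),
                           highwayWidth = 30, habitat = list(),
                           extent = NULL) {
  ports <- as.matrix(ports)
  if (ncol(ports) && ncol(ports) != 2) stop("ports must be n x 2")
  toMat <- function(l) lapply(l, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2, all(is.finite(m)))
    m
  })
  if (is.null(extent)) {
    allXY <- rbind(ports, do.call(rbind, c(toMat(rivers), toMat(highways),
                                           toMat(railways),
                                           list(matrix(numeric(0), 0, 2)))))
    extent <- if (nrow(allXY))
      c(min(allXY[, 1]), max(allXY[, 1]), min(allXY[, 2]), max(allXY[, 2]))
    else c(0, 1, 0, 1)
  }
  new("LandscapeModel", ports = ports, rivers = toMat(rivers),
      highways = toMat(highways), railways = toMat(railways),
      highwayWidth = highwayWidth, habitat = habitat,
      extent = as.numeric(extent))
}

setMethod("show", "LandscapeModel", function(object) {
  cat("LandscapeModel:", nrow(object@ports), "ports;",
      length(object@rivers), "river and", length(object@highways),
      "highway polylines",
      if (length(object@habitat)) "; habitat raster attached" else "", "\n")
})

# ---- geometry primitives -------------------------------------------------

# minimum distance from each point (n x 2) to segment (a, b)
.pointSegDist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- a[1] + t * ab[1] - pts[, 1]
  dy <- a[2] + t * ab[2] - pts[, 2]
  sqrt(dx^2 + dy^2)
}

# minimum distance from points to a list of polylines
.pointPolylinesDist <- function(pts, polylines) {
  pts <- rbind(pts)
  best <- rep(Inf, nrow(pts))
  for (pl in polylines) {
    if (nrow(pl) < 2) {
      warning("degenerate polyline ignored")
      next
    }
    for (s in seq_len(nrow(pl) - 1)) {
      best <- pmin(best, .pointSegDist(pts, pl[s, ], pl[s + 1, ]))
    }
  }
  best
}

# ---- isolation scores ----------------------------------------------------

#' Port isolation: log distance to the nearest shipping terminal
#'
#' Natural log of (Euclidean distance to the nearest port + 1 m); the one
#' metre offset makes a point on a port score exactly 0 and keeps the log
#' finite.
#'
#' @param points n x 2 matrix of individual coordinates (m)
#' @param ports p x 2 matrix of port coordinates
#' @export
portIsolation <- function(points, ports) {
  ports <- rbind(ports)
  if (!nrow(ports)) stop("at least one port is required")
  points <- rbind(points)
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(ports)))
    d <- pmin(d, sqrt((points[, 1] - ports[i, 1])^2 +
                      (points[, 2] - ports[i, 2])^2))
  log(d + 1)
}

#' River isolation: log distance to the nearest river segment
#'
#' Natural log of (point-to-polyline distance + 1 m); distance to a
#' polyline is the minimum over its segments of the perpendicular/endpoint
#' distance.
#'
#' @param points n x 2 matrix
#' @param rivers list of polylines
#' @export
riverIsolation <- function(points, rivers) {
  if (!length(rivers)) stop("at least one river polyline is required")
  log(.pointPolylinesDist(points, rivers) + 1)
}

#' Highway isolation: root of the disc area clear of the highway network
#'
#' Buffers every highway polyline by half the nominal carriageway width on
#' each side and scores each point as the square root of the area within
#' `radius` of the point that is not covered by any buffer. The area is
#' integrated on a regular grid of cell centres (`gridStep` m); with no
#' highway in range the score is \eqn{\sqrt{\pi r^2}} (about 1772.45 m for
#' r = 1 km) and a fully covered disc scores 0. More highway within the
#' disc always lowers the score.
#'
#' @param points n x 2 matrix
#' @param highways list of polylines
#' @param radius disc radius, metres (default 1000)
#' @param width total highway width, metres (default 30)
#' @param gridStep integration cell size, metres (default 5)
#' @export
highwayIsolation <- function(points, highways, radius = 1000, width = 30,
                             gridStep = 5) {
  stopifnot(radius > 0, width > 0)
  points <- rbind(points)
  highways <- Filter(function(pl) {
    ok <- nrow(pl) >= 2 && sum(sqrt(rowSums(diff(pl)^2))) > 0
    if (!ok) warning("degenerate polyline ignored")
    ok
  }, highways)
  g <- seq(-radius + gridStep / 2, radius - gridStep / 2, by = gridStep)
  cells <- expand.grid(dx = g, dy = g)
  inDisc <- cells$dx^2 + cells$dy^2 <= radius^2
  cells <- as.matrix(cells[inDisc, ])
  cellArea <- gridStep^2
  half <- width / 2
  vapply(seq_len(nrow(points)), function(i) {
    ctr <- points[i, ]
    near <- Filter(function(pl) {
      min(.pointPolylinesDist(rbind(ctr), list(pl))) <= radius + half
    }, highways)
    if (!length(near)) return(sqrt(pi * radius^2))
    abs_cells <- cbind(cells[, 1] + ctr[1], cells[, 2] + ctr[2])
    covered <- .pointPolylinesDist(abs_cells, near) <= half
    sqrt(max(0, sum(!covered) * cellArea))
  }, numeric(1))
}

#' Additive pairwise isolation matrix
#'
#' Off-diagonal entries sum the two individual isolation scores, except that
#' pairs from the same sample site are assigned a total isolation of zero
#' (movement within a site requires no network transit); the diagonal is
#' zero.
#'
#' @param scores named per-individual isolation scores
#' @param siteMap named vector individual -> site
#' @return [PairwiseMatrix-class] of kind `"isolation"`
#' @export
additivePairMatrix <- function(scores, siteMap) {
  ids <- names(scores)
  stopifnot(!is.null(ids), all(ids %in% names(siteMap)))
  m <- outer(scores, scores, "+")
  same <- outer(siteMap[ids], siteMap[ids], "==")
  m[same] <- 0
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  PairwiseMatrix(m, kind = "isolation")
}

#' Pairwise barrier matrix from per-individual position codes
#'
#' Individuals are coded by an integer tier describing their position
#' relative to a barrier set (e.g. highway tiers 0-2, river tiers 0-3); the
#' pairwise value is the absolute code difference, i.e. the number of
#' barrier tiers separating the pair.
#'
#' @param codes named integer per-individual barrier codes
#' @return [PairwiseMatrix-class] of kind `"barrier"`
#' @export
barrierPairMatrix <- function(codes) {
  stopifnot(!is.null(names(codes)), all(codes == round(codes)))
  m <- abs(outer(codes, codes, "-"))
  dimnames(m) <- list(names(codes), names(codes))
  PairwiseMatrix(m, kind = "barrier")
}

# ---- ordinary kriging ----------------------------------------------------

#' Fit an exponential semivariogram by weighted least squares
#'
#' Empirical semivariances are computed in `nBins` equal-width distance
#' bins and the exponential model
#' \eqn{\gamma(h) = nugget + (sill - nugget)(1 - e^{-h/range})} is fitted by
#' least squares weighted by bin pair counts.
#'
#' @param obs data.frame/matrix with columns x, y, value
#' @param nBins number of distance bins (default 12)
#' @return list with `nugget`, `sill`, `range`
#' @export
fitExponentialVariogram <- function(obs, nBins = 12) {
  obs <- as.data.frame(obs)
  stopifnot(nrow(obs) >= 2)
  d <- as.matrix(dist(obs[, c("x", "y")]))
  sq <- outer(obs$value, obs$value, "-")^2 / 2
  ut <- upper.tri(d)
  h <- d[ut]; gam <- sq[ut]
  maxh <- max(h) * 0.75                     # classical working cutoff
  bins <- cut(h, breaks = seq(0, maxh, length.out = nBins + 1),
              include.lowest = TRUE)
  emp <- tapply(gam, bins, mean)
  mid <- tapply(h, bins, mean)
  cnt <- tapply(h, bins, length)
  ok <- !is.na(emp)
  emp <- emp[ok]; mid <- mid[ok]; cnt <- cnt[ok]
  sill0 <- var(obs$value); range0 <- maxh / 3
  obj <- function(par) {
    nug <- exp(par[1]); psill <- exp(par[2]); rng <- exp(par[3])
    mod <- nug + psill * (1 - exp(-mid / rng))
    sum(cnt * (emp - mod)^2)
  }
  fit <- optim(log(c(sill0 / 10 + 1e-9, sill0 + 1e-9, range0)), obj,
               method = "Nelder-Mead")
  nug <- exp(fit$par[1]); psill <- exp(fit$par[2]); rng <- exp(fit$par[3])
  list(nugget = nug, sill = nug + psill, range = rng)
}

.expGamma <- function(h, vg) {
  vg$nugget + (vg$sill - vg$nugget) * (1 - exp(-h / vg$range))
}

#' Ordinary kriging with an exponential model and nearest-neighbour search
#'
#' For each target the ordinary-kriging system is solved on the
#' `nNeighbors` nearest observations under the fitted exponential
#' semivariogram, with the Lagrange constraint forcing weights to sum to 1
#' (so the predictor is exact at observation points when the nugget is 0).
#' Singular systems are ridge-regularised with a warning.
#'
#' @param obs data.frame with columns x, y, value
#' @param targets n x 2 matrix of prediction locations
#' @param variogram list(nugget, sill, range); fitted from `obs` when NULL
#' @param nNeighbors neighbours used per target (default 36)
#' @return list with `estimate` (per target), `variogram`, and `weights`
#'   (matrix of kriging weights, one row per target)
#' @export
ordinaryKriging <- function(obs, targets, variogram = NULL,
                            nNeighbors = 36) {
  obs <- as.data.frame(obs)
  stopifnot(nrow(obs) >= 2)
  if (is.null(variogram)) variogram <- fitExponentialVariogram(obs)
  stopifnot(variogram$sill > 0, variogram$range > 0, variogram$nugget >= 0)
  targets <- rbind(targets)
  nn <- min(nNeighbors, nrow(obs))
  est <- numeric(nrow(targets))
  W <- matrix(NA_real_, nrow(targets), nrow(obs))
  for (t in seq_len(nrow(targets))) {
    dAll <- sqrt((obs$x - targets[t, 1])^2 + (obs$y - targets[t, 2])^2)
    idx <- order(dAll)[seq_len(nn)]
    sub <- obs[idx, ]
    G <- .expGamma(as.matrix(dist(sub[, c("x", "y")])), variogram)
    diag(G) <- 0
    A <- rbind(cbind(G, 1), c(rep(1, nn), 0))
    b <- c(.expGamma(dAll[idx], variogram), 1)
    w <- tryCatch(solve(A, b), error = function(e) {
      warning("singular kriging system: ridge-regularised solve")
      solve(A + diag(1e-8, nn + 1), b)
    })
    est[t] <- sum(w[seq_len(nn)] * sub$value)
    W[t, idx] <- w[seq_len(nn)]
  }
  list(estimate = est, variogram = variogram, weights = W)
}

#' Krige a surface onto a regular raster
#'
#' @param obs data.frame with x, y, value
#' @param extent c(xmin, xmax, ymin, ymax)
#' @param cellSize raster cell size (m)
#' @param ... passed to [ordinaryKriging()]
#' @return habitat raster list(x, y, values) usable in a
#'   [LandscapeModel-class]
#' @export
krigeRaster <- function(obs, extent, cellSize, ...) {
  xs <- seq(extent[1] + cellSize / 2, extent[2], by = cellSize)
  ys <- seq(extent[3] + cellSize / 2, extent[4], by = cellSize)
  tg <- as.matrix(expand.grid(x = xs, y = ys))
  ok <- ordinaryKriging(obs, tg, ...)
  list(x = xs, y = ys,
       values = matrix(ok$estimate, length(xs), length(ys)))
}

#' Mean surface value within a radius of a point
#'
#' Averages raster values over the cells whose centres fall inside the
#' disc. Errors if no cell centre is covered.
#'
#' @param raster list(x, y, values) as in [LandscapeModel-class] habitat
#' @param point length-2 coordinate
#' @param radius metres (default 1000)
#' @export
meanWithinRadius <- function(raster, point, radius = 1000) {
  dx <- outer(raster$x - point[1], rep(1, length(raster$y)))
  dy <- outer(rep(1, length(raster$x)), raster$y - point[2])
  inDisc <- dx^2 + dy^2 <= radius^2
  if (!any(inDisc)) stop("no raster cell centre within radius of point")
  mean(raster$values[inDisc])
}

# ---- GeoJSON / ASCII-grid interchange ------------------------------------

#' Read landscape geometry from a GeoJSON feature collection
#'
#' Points become ports; LineString/MultiLineString features become rivers,
#' highways or railways according to their `layer` property (values
#' `"river"`, `"highway"`, `"railway"`; unlabelled lines default to
#' highways). Coordinates must already be in a projected CRS in metres.
#'
#' @param path GeoJSON file
#' @param highwayWidth passed to [LandscapeModel()]
#' @export
readLandscapeGeoJSON <- function(path, highwayWidth = 30) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  ports <- list(); lines <- list(river = list(), highway = list(),
                                 railway = list())
  for (f in j$features) {
    geom <- f$geometry
    layer <- tolower(f$properties$layer %||% "highway")
    coordsOfLine <- function(cc)
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    if (geom$type == "Point") {
      ports[[length(ports) + 1]] <- c(geom$coordinates[[1]],
                                      geom$coordinates[[2]])
    } else if (geom$type == "LineString") {
      lines[[layer]] <- c(lines[[layer]], list(coordsOfLine(geom$coordinates)))
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates)
        lines[[layer]] <- c(lines[[layer]], list(coordsOfLine(part)))
    }
  }
  LandscapeModel(ports = do.call(rbind, c(ports, list(matrix(numeric(0), 0, 2)))),
                 rivers = lines$river, highways = lines$highway,
                 railways = lines$railway, highwayWidth = highwayWidth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write landscape geometry as GeoJSON
#' @param model a [LandscapeModel-class]
#' @param path output file
#' @export
writeLandscapeGeoJSON <- function(model, path) {
  feat <- list()
  addLine <- function(pl, layer) {
    list(type = "Feature", properties = list(layer = layer),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pl)),
                                              function(i) as.numeric(pl[i, ]))))
  }
  for (i in seq_len(nrow(model@ports)))
    feat[[length(feat) + 1]] <- list(
      type = "Feature", properties = list(layer = "port"),
      geometry = list(type = "Point",
                      coordinates = as.numeric(model@ports[i, ])))
  for (pl in model@rivers) feat[[length(feat) + 1]] <- addLine(pl, "river")
  for (pl in model@highways) feat[[length(feat) + 1]] <- addLine(pl, "highway")
  for (pl in model@railways) feat[[length(feat) + 1]] <- addLine(pl, "railway")
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a raster as an ESRI ASCII grid
#' @param raster list(x, y, values)
#' @param path output file
#' @export
writeAsciiGrid <- function(raster, path) {
  cell <- raster$x[2] - raster$x[1]
  hdr <- c(paste("ncols", length(raster$x)),
           paste("nrows", length(raster$y)),
           paste("xllcorner", raster$x[1] - cell / 2),
           paste("yllcorner", raster$y[1] - cell / 2),
           paste("cellsize", cell),
           "NODATA_value -9999")
  rows <- apply(t(raster$values)[rev(seq_along(raster$y)), , drop = FALSE],
                1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
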