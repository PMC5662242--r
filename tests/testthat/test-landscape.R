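test_that("port and river isolation equal brute-force nearest-feature distances", {
  expect_equal(portIsolation(cbind(0, 0), cbind(0, 0)), 0)
  expect_equal(portIsolation(cbind(0, 0), cbind(1000, 0)), log(1001))
  expect_error(portIsolation(cbind(0, 0), matrix(numeric(0), 0, 2)),
               "at least one port")
  set.seed(31)
  pts <- cbind(runif(20, 0, 5000), runif(20, 0, 5000))
  ports <- cbind(runif(5, 0, 5000), runif(5, 0, 5000))
  sc <- portIsolation(pts, ports)
  oracle <- vapply(seq_len(20), function(i)
    log(min(sqrt((ports[, 1] - pts[i, 1])^2 +
                 (ports[, 2] - pts[i, 2])^2)) + 1), 0)
  expect_equal(sc, oracle, tolerance = 1e-12)

  # river: a point on the segment, a perpendicular offset, and a
  # multi-segment brute force
  seg <- list(cbind(c(-1000, 1000), c(0, 0)))
  expect_equal(riverIsolation(cbind(0, 0), seg), 0)
  expect_equal(riverIsolation(cbind(0, 500), seg), log(501))
  rivers <- list(cbind(runif(4, 0, 5000), runif(4, 0, 5000)),
                 cbind(runif(3, 0, 5000), runif(3, 0, 5000)))
  segDist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t)); sqrt(sum((a + t * ab - p)^2))
  }
  sc2 <- riverIsolation(pts, rivers)
  oracle2 <- vapply(seq_len(20), function(i) {
    best <- Inf
    for (pl in rivers) for (s in seq_len(nrow(pl) - 1))
      best <- min(best, segDist(pts[i, ], pl[s, ], pl[s + 1, ]))
    log(best + 1)
  }, 0)
  expect_equal(sc2, oracle2, tolerance = 1e-12)
})

test_that("highway isolation matches closed forms and a Monte-Carlo area oracle", {
  # empty disc
  expect_equal(highwayIsolation(cbind(0, 0), list(), 1000, 30),
               sqrt(pi * 1e6), tolerance = 1e-9)
  # single straight highway through the centre vs Monte-Carlo integration
  hw <- list(cbind(c(-5000, 5000), c(0, 0)))
  sc <- highwayIsolation(cbind(0, 0), hw, 1000, 30, gridStep = 4)
  set.seed(32)
  x <- runif(4e5, -1000, 1000); y <- runif(4e5, -1000, 1000)
  mc <- sqrt(mean(x^2 + y^2 <= 1e6 & abs(y) > 15) * 4e6)
  expect_equal(sc, mc, tolerance = 0.01)
  # fully covered disc scores zero
  dense <- lapply(seq(-1000, 1000, by = 25), function(y0)
    cbind(c(-2000, 2000), c(y0, y0)))
  expect_equal(highwayIsolation(cbind(0, 0), dense, 1000, 30,
                                gridStep = 10), 0)
  # monotone: adding highway length never increases the score
  sc2 <- highwayIsolation(cbind(0, 0),
                          c(hw, list(cbind(c(0, 0), c(-5000, 5000)))),
                          1000, 30, gridStep = 4)
  expect_lte(sc2, sc)
})

test_that("isolation scores are invariant under rigid motions of the scene", {
  set.seed(33)
  pts <- cbind(runif(6, 0, 3000), runif(6, 0, 3000))
  ports <- cbind(runif(3, 0, 3000), runif(3, 0, 3000))
  rivers <- list(cbind(runif(5, 0, 3000), runif(5, 0, 3000)))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(1234, -987)
  mv <- function(m) sweep(m %*% t(R), 2, -shift)
  expect_equal(portIsolation(mv(pts), mv(ports)),
               portIsolation(pts, ports), tolerance = 1e-9)
  expect_equal(riverIsolation(mv(pts), lapply(rivers, mv)),
               riverIsolation(pts, rivers), tolerance = 1e-9)
  hw <- list(cbind(c(-4000, 4000), c(200, 100)))
  expect_equal(highwayIsolation(mv(pts[1:2, ]), lapply(hw, mv),
                                gridStep = 10),
               highwayIsolation(pts[1:2, ], hw, gridStep = 10),
               tolerance = 20)   # grid is axis-aligned; small re-binning error
})

test_that("additive pair matrices zero same-site pairs and scale linearly", {
  scores <- c(a = 2, b = 3, c = 1)
  sites <- c(a = "S1", b = "S2", c = "S1")
  m <- as.matrix(additivePairMatrix(scores, sites))
  expect_equal(m["a", "b"], 5)
  expect_equal(m["a", "c"], 0)            # same site
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m))
  m3 <- as.matrix(additivePairMatrix(3 * scores, sites))
  expect_equal(m3, 3 * m)
})

test_that("barrier matrices count tiers separating each pair", {
  codes <- c(a = 0, b = 2, c = 1, d = 1, e = 3)
  m <- as.matrix(barrierPairMatrix(codes))
  expect_equal(m["a", "b"], 2)
  expect_equal(m["c", "d"], 0)
  for (i in names(codes)) for (j in names(codes))
    expect_equal(m[i, j], abs(codes[[i]] - codes[[j]]))
})

test_that("ordinary kriging is exact, symmetric, constrained and beats inverse distance", {
  set.seed(34)
  obs <- data.frame(x = runif(30, 0, 1000), y = runif(30, 0, 1000),
                    value = rnorm(30))
  vg <- list(nugget = 0, sill = 1, range = 300)
  # exactness at an observation with zero nugget
  kr <- ordinaryKriging(obs, as.matrix(obs[7, 1:2]), vg)
  expect_equal(kr$estimate, obs$value[7], tolerance = 1e-8)
  # two observations, target midway: symmetric weights
  obs2 <- data.frame(x = c(0, 1000), y = 0, value = c(2, 8))
  kr2 <- ordinaryKriging(obs2, cbind(500, 0), vg)
  expect_equal(unname(kr2$weights[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(kr2$estimate, 5)
  # weights sum to one at arbitrary targets (Lagrange constraint)
  tg <- cbind(runif(10, 0, 1000), runif(10, 0, 1000))
  kr3 <- ordinaryKriging(obs, tg, vg, nNeighbors = 12)
  expect_equal(unname(rowSums(kr3$weights, na.rm = TRUE)), rep(1, 10),
               tolerance = 1e-9)
  # fitted-variogram kriging of a smooth surface beats an IDW baseline
  f <- function(x, y) sin(x / 300) + cos(y / 300)
  obs3 <- data.frame(x = runif(50, 0, 2000), y = runif(50, 0, 2000))
  obs3$value <- f(obs3$x, obs3$y)
  tg3 <- cbind(runif(60, 200, 1800), runif(60, 200, 1800))
  est <- ordinaryKriging(obs3, tg3, nNeighbors = 36)$estimate
  idw <- vapply(seq_len(nrow(tg3)), function(i) {
    d <- sqrt((obs3$x - tg3[i, 1])^2 + (obs3$y - tg3[i, 2])^2)
    w <- 1 / (d + 1)^2
    sum(w * obs3$value) / sum(w)
  }, 0)
  truth <- f(tg3[, 1], tg3[, 2])
  expect_lt(mean(abs(est - truth)), mean(abs(idw - truth)))
})

test_that("radius means agree with brute-force cell loops", {
  cellSeq <- seq(-2000, 2000, by = 50) + 25
  ras <- list(x = cellSeq, y = cellSeq,
              values = matrix(3.7, length(cellSeq), length(cellSeq)))
  expect_equal(meanWithinRadius(ras, c(0, 0), 1000), 3.7)
  ras$values <- outer(ras$x, ras$y, function(x, y) as.numeric(x > 0))
  expect_equal(meanWithinRadius(ras, c(0, 0), 1000), 0.5, tolerance = 0.03)
  set.seed(35)
  ras$values <- matrix(rnorm(length(cellSeq)^2), length(cellSeq))
  pt <- c(333, -777); rad <- 900
  got <- meanWithinRadius(ras, pt, rad)
  acc <- c()
  for (i in seq_along(ras$x)) for (j in seq_along(ras$y))
    if ((ras$x[i] - pt[1])^2 + (ras$y[j] - pt[2])^2 <= rad^2)
      acc <- c(acc, ras$values[i, j])
  expect_equal(got, mean(acc), tolerance = 1e-12)
  expect_error(meanWithinRadius(ras, c(1e6, 1e6), 100), "no raster cell")
})

test_that("GeoJSON and ASCII-grid round trips preserve the geometry", {
  ls <- generateLandscape(5, c(0, 10000, 0, 10000), "unconfounded", seed = 4)
  p <- file.path(tempdir(), "scene.geojson")
  writeLandscapeGeoJSON(ls, p)
  back <- readLandscapeGeoJSON(p)
  expect_equal(back@ports, ls@ports, ignore_attr = TRUE)
  expect_length(back@rivers, length(ls@rivers))
  expect_length(back@highways, length(ls@highways))
  expect_equal(back@rivers[[1]], ls@rivers[[1]], ignore_attr = TRUE)
  pg <- file.path(tempdir(), "grid.asc")
  writeAsciiGrid(ls@habitat, pg)
  hdr <- readLines(pg, n = 6)
  expect_match(hdr[1], "^ncols 10$")
  expect_match(hdr[5], "^cellsize 1000$")
})
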