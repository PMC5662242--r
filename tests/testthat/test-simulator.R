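test_that("landscape generation is seed-deterministic and mode-aware", {
  ext <- c(0, 20000, 0, 20000)
  ls1 <- generateLandscape(5, ext, "unconfounded", seed = 8)
  ls2 <- generateLandscape(5, ext, "unconfounded", seed = 8)
  f1 <- file.path(tempdir(), "a.geojson"); f2 <- file.path(tempdir(), "b.geojson")
  writeLandscapeGeoJSON(ls1, f1); writeLandscapeGeoJSON(ls2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_equal(nrow(ls1@ports), 5L)
  # confounded port isolation tracks the x coordinate; unconfounded does not
  rC <- rU <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    pts <- cbind(runif(200, 0, 20000), runif(200, 0, 20000))
    lc <- generateLandscape(5, ext, "confounded", seed = s)
    lu <- generateLandscape(5, ext, "unconfounded", seed = s)
    rC[s] <- cor(portIsolation(pts, lc@ports), pts[, 1])
    rU[s] <- cor(portIsolation(pts, lu@ports), pts[, 1])
  }
  expect_true(all(rC > 0.5))
  expect_true(all(abs(rU) < 0.3))
  expect_lt(mean(abs(rU)), 0.2)
})

test_that("location placement respects strata weights, jitter bounds and uniqueness", {
  # equal-area strata with representative values 1 / 3 / 5
  ras <- list(x = seq(50, 2950, by = 100), y = seq(50, 2950, by = 100))
  ras$values <- matrix(rep(c(1, 3, 5), each = 300), 30, 30)
  pl <- placeLocations(ras, 10000L, seed = 9)
  stratum <- findInterval(pl$points[, 2], c(1000, 2000))   # by y band
  counts <- table(stratum)
  gof <- stats::chisq.test(counts, p = c(1, 3, 5) / 9)
  expect_gt(gof$p.value, 0.001)
  expect_false(anyDuplicated(pl$points) > 0)
  # jitter bound and focal-only placement
  focal <- cbind(runif(40, 500, 2500), runif(40, 500, 2500))
  pl2 <- placeLocations(ras, 40L, focalPoints = focal, jitterRadius = 250,
                        seed = 10)
  expect_equal(nrow(pl2$points), 40L)
  disp <- sqrt(rowSums((pl2$points - focal)^2))
  expect_true(all(disp <= 250))
  expect_error(placeLocations(ras, 10L, focalPoints = focal),
               "less than the number of focal")
})

test_that("forward simulation is reproducible, Mendelian and starts at maximum diversity", {
  cfg <- simulationConfig(nLocations = 120L, nFocal = 0L, nLoci = 150L,
                          generations = 8L, dispersalScale = 800,
                          seed = 31L)
  set.seed(1); locs <- cbind(runif(120, 0, 10000), runif(120, 0, 10000))
  p1 <- runSimulation(cfg, locs)
  p2 <- runSimulation(cfg, locs)
  expect_identical(p1@maternal, p2@maternal)
  expect_identical(p1@paternal, p2@paternal)
  # generation 0 allele frequencies hover around 0.5
  expect_equal(p1@hetTrajectory[1], 0.5, tolerance = 0.02)
  # offspring alleles are copies of recorded parents' alleles
  par <- p1@parentage
  for (i in sample(120, 20)) {
    mo <- par$mother[i]; fa <- par$father[i]
    okM <- p1@maternal[i, ] == p1@parentMaternal[mo, ] |
           p1@maternal[i, ] == p1@parentPaternal[mo, ]
    okP <- p1@paternal[i, ] == p1@parentMaternal[fa, ] |
           p1@paternal[i, ] == p1@parentPaternal[fa, ]
    expect_true(all(okM) && all(okP))
  }
  # no selfing
  expect_true(all(par$mother != par$father))
})

test_that("heterozygosity decays at the neutral drift rate under panmixia", {
  cfg <- simulationConfig(nLocations = 100L, nFocal = 0L, nLoci = 500L,
                          generations = 50L, dispersalScale = Inf,
                          seed = 32L)
  pop <- runSimulation(cfg)
  expected <- 0.5 * (1 - 1 / (2 * 100))^50
  expect_equal(pop@hetTrajectory[51], expected, tolerance = 0.1 * expected)
})

test_that("panmictic populations show no spatial structure in an AMOVA", {
  cfg <- simulationConfig(nLocations = 150L, nFocal = 0L, nLoci = 200L,
                          generations = 10L, dispersalScale = Inf,
                          seed = 33L)
  set.seed(2); locs <- cbind(runif(150, 0, 10000), runif(150, 0, 10000))
  pop <- runSimulation(cfg, locs)
  gm <- samplePopulation(pop, 1:150,
                         sites = rep(paste0("S", 1:10), each = 15))
  res <- amova(roussetA(gm), siteOf(gm), nPerm = 99, seed = 1)
  expect_lt(res@etaSq, 0.02)
})

test_that("population sampling returns consistent dosages and is stateless", {
  cfg <- simulationConfig(nLocations = 60L, nFocal = 0L, nLoci = 40L,
                          generations = 3L, dispersalScale = 1000,
                          seed = 34L)
  pop <- runSimulation(cfg)
  gm <- samplePopulation(pop, 1:60)
  expect_equal(dim(dosageMatrix(gm)), c(60L, 40L))
  expect_equal(unname(dosageMatrix(gm)),
               unname(pop@maternal + pop@paternal))
  gm2 <- samplePopulation(pop, 1:60)
  expect_identical(dosageMatrix(gm), dosageMatrix(gm2))
  expect_error(samplePopulation(pop, c(1, 61)), "outside")
  sub <- samplePopulation(pop, c(5, 7))
  expect_equal(coordsOf(sub)[, "x"], pop@locations[c(5, 7), 1],
               ignore_attr = TRUE)
})

test_that("pedigree fixtures share parents as labelled and segregate Mendelianly", {
  ped <- generatePedigreeFixture(nFamilies = 5, familySizes = 3,
                                 nUnrelated = 4, nLoci = 120,
                                 nHalfSibFamilies = 4, seed = 35)
  tr <- ped$truth
  fs <- tr[tr$type == "full-sib-family", ]
  for (fam in unique(fs$family)) {
    expect_length(unique(fs$mother[fs$family == fam]), 1L)
    expect_length(unique(fs$father[fs$family == fam]), 1L)
  }
  hs <- tr[tr$type == "half-sib-family", ]
  for (fam in unique(hs$family)) {
    expect_length(unique(hs$mother[hs$family == fam]), 1L)
    expect_equal(length(unique(hs$father[hs$family == fam])),
                 sum(hs$family == fam))
  }
  # Mendelian consistency of every child with its recorded parents
  d <- dosageMatrix(ped$genotypes)
  gamete <- function(p) rbind(p[1, ], p[2, ])    # two possible alleles
  for (id in tr$id) {
    mo <- ped$parents[[tr$mother[tr$id == id]]]
    fa <- ped$parents[[tr$father[tr$id == id]]]
    child <- d[id, ]
    lo <- (mo[1, ] == 1 | mo[2, ] == 1) * 0 + pmin(mo[1, ], mo[2, ]) +
          pmin(fa[1, ], fa[2, ])
    hi <- pmax(mo[1, ], mo[2, ]) + pmax(fa[1, ], fa[2, ])
    expect_true(all(child >= lo & child <= hi))
  }
})
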