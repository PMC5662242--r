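randSym <- function(n, labels = sprintf("i%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2)
  PairwiseMatrix(m + t(m))
}

test_that("Mantel statistic is a matrix correlation with affine invariance", {
  set.seed(41)
  A <- randSym(15)
  same <- mantelTest(A, A, nPerm = 99, seed = 1)
  expect_equal(same@r, 1)
  aff <- PairwiseMatrix(2 * as.matrix(A) + 3)
  expect_equal(mantelTest(A, aff, nPerm = 99, seed = 1)@r, 1)
  # agrees with vegan on statistic and roughly on significance
  B <- randSym(15)
  mine <- mantelTest(A, B, nPerm = 999, seed = 2)
  vg <- vegan::mantel(as.matrix(A), as.matrix(B), permutations = 999)
  expect_equal(mine@r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(mine@p - vg$signif), 0.1)
  # constant matrix is rejected
  expect_error(mantelTest(A, PairwiseMatrix(matrix(1, 15, 15) - diag(15),
                                            labels = pairLabels(A)),
                          nPerm = 99),
               "constant")
})

test_that("partial Mantel reduces to plain Mantel under degenerate conditioning", {
  set.seed(42)
  A <- randSym(15); B <- randSym(15)
  Cc <- PairwiseMatrix(matrix(2, 15, 15) - 2 * diag(15),
                       labels = pairLabels(A))
  expect_warning(res <- partialMantelTest(A, B, Cc, nPerm = 99, seed = 1),
                 "constant conditioning")
  expect_equal(res@r, mantelTest(A, B, nPerm = 99, seed = 1)@r)
  # conditioning on an unrelated matrix leaves r essentially unchanged
  Cu <- randSym(15, pairLabels(A))
  r0 <- mantelTest(A, B, nPerm = 99, seed = 1)@r
  r1 <- partialMantelTest(A, B, Cu, nPerm = 99, seed = 1)@r
  expect_lt(abs(r1 - r0), 0.15)
  # A = B = C: residuals vanish, handled without crashing
  expect_warning(deg <- partialMantelTest(A, A, A, nPerm = 99, seed = 1),
                 "constant residual")
  expect_equal(deg@r, 0)
})

test_that("permutation tests hold their nominal size under exchangeable nulls", {
  set.seed(43)
  nRep <- 300
  rejM <- rejP <- logical(nRep)
  for (r in seq_len(nRep)) {
    A <- randSym(12); B <- randSym(12)
    rejM[r] <- mantelTest(A, B, nPerm = 99)@p < 0.05
    # A and B driven by a shared conditioning matrix, independent given C
    Cm <- as.matrix(randSym(12))
    mk <- function() {
      e <- matrix(0, 12, 12); e[upper.tri(e)] <- rnorm(66)
      PairwiseMatrix(1.5 * Cm + e + t(e), labels = rownames(Cm))
    }
    rejP[r] <- partialMantelTest(mk(), mk(), PairwiseMatrix(Cm),
                                 nPerm = 99)@p < 0.05
  }
  ciHalf <- 1.96 * sqrt(0.05 * 0.95 / nRep)
  expect_lt(abs(mean(rejM) - 0.05), ciHalf + 0.01)
  expect_lt(abs(mean(rejP) - 0.05), ciHalf + 0.01)
})

test_that("PCNM matches a direct truncated eigendecomposition oracle", {
  set.seed(44)
  pts <- cbind(runif(12, 0, 1000), runif(12, 0, 1000))
  D <- as.matrix(dist(pts))
  basis <- pcnmBasis(PairwiseMatrix(D))
  # oracle: truncate at the longest minimum-spanning-tree edge, 4t beyond,
  # double-centre, eigendecompose
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                           mode = "undirected")
  t0 <- max(igraph::E(igraph::mst(g))$weight)
  expect_equal(basis@truncation, t0, tolerance = 1e-9)
  Dt <- D; Dt[Dt > t0] <- 4 * t0
  A <- -0.5 * Dt^2
  Bc <- sweep(A, 1, rowMeans(A)); Bc <- sweep(Bc, 2, colMeans(Bc))
  ev <- eigen((Bc + t(Bc)) / 2, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(ev$values)
  expect_equal(basis@values, ev$values[pos], tolerance = 1e-8)
  for (i in seq_len(sum(pos)))
    expect_equal(abs(cor(basis@vectors[, i], ev$vectors[, i])), 1,
                 tolerance = 1e-6)
  # orthonormal
  G <- crossprod(basis@vectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-9, ignore_attr = TRUE)
  # duplicate points do not produce NaN
  pts2 <- rbind(pts, pts[1, ])
  b2 <- pcnmBasis(PairwiseMatrix(as.matrix(dist(pts2))))
  expect_false(any(is.nan(b2@vectors)))
})

test_that("dbRDA reproduces classical RDA on Euclidean embeddings", {
  set.seed(45)
  n <- 24
  Yraw <- matrix(rnorm(n * 5), n, 5)
  X1 <- rnorm(n); X2 <- rnorm(n); Z <- rnorm(n)
  D <- PairwiseMatrix(as.matrix(dist(Yraw)))
  fit <- fitDbrda(D, list(x1 = X1, x2 = X2), nPerm = 99, seed = 1)
  vr <- vegan::rda(Yraw ~ X1 + X2)
  expect_equal(fit@r2, vegan::RsquareAdj(vr)$r.squared, tolerance = 1e-9)
  expect_equal(fit@adjR2, vegan::RsquareAdj(vr)$adj.r.squared,
               tolerance = 1e-9)
  expect_equal(fit@constrainedInertia / (n - 1), vr$CCA$tot.chi,
               tolerance = 1e-9)
  expect_equal(unname(fit@vif), unname(vegan::vif.cca(vr)),
               tolerance = 1e-6)
  # conditioned model against capscale
  fc <- fitDbrda(D, list(x1 = X1, x2 = X2), conditional = Z, nPerm = 99,
                 seed = 1)
  vc <- vegan::capscale(dist(Yraw) ~ X1 + X2 + Condition(Z))
  expect_equal(fc@constrainedInertia / fc@totalInertia,
               vc$CCA$tot.chi / vc$tot.chi, tolerance = 1e-9)
  # inertia decomposition is exact (validity enforces it too)
  expect_equal(fc@conditionalInertia + fc@constrainedInertia +
                 fc@unconstrainedInertia, fc@totalInertia,
               tolerance = 1e-8 * fc@totalInertia)
  # empty explanatory list
  e <- fitDbrda(D, list(), nPerm = 0)
  expect_equal(e@constrainedInertia, 0)
  expect_equal(e@adjR2, 0)
})

test_that("orthogonal dbRDA terms show null effect sizes and calibrated p-values", {
  set.seed(46)
  ps <- etas <- numeric(30)
  for (r in seq_len(30)) {
    Yraw <- matrix(rnorm(20 * 3), 20, 3)
    D <- PairwiseMatrix(as.matrix(dist(Yraw)))
    fit <- fitDbrda(D, list(noise = rnorm(20)), nPerm = 99)
    ps[r] <- fit@terms$p
    etas[r] <- fit@terms$etaSq
  }
  expect_lt(mean(etas), 0.15)
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)
})

test_that("forward selection prefers informative terms and never decreases fit", {
  set.seed(47)
  hits <- 0
  for (r in seq_len(40)) {
    Yraw <- matrix(rnorm(25 * 3), 25, 3)
    signal <- Yraw[, 1] + rnorm(25, 0, 0.5)
    D <- PairwiseMatrix(as.matrix(dist(Yraw)))
    sel <- forwardSelectDbrda(D, list(informative = signal,
                                      noise = rnorm(25)), nPerm = 0)
    if (length(sel$order) && sel$order[1] == "informative") hits <- hits + 1
    if (length(sel$path) > 1) expect_true(all(diff(sel$path) > 0))
  }
  expect_gte(hits / 40, 0.95)
  # a duplicated candidate is never accepted twice
  set.seed(48)
  Yraw <- matrix(rnorm(25 * 3), 25, 3)
  v <- Yraw[, 1] + rnorm(25, 0, 0.3)
  sel2 <- suppressWarnings(
    forwardSelectDbrda(PairwiseMatrix(as.matrix(dist(Yraw))),
                       list(a = v, b = v), nPerm = 0))
  expect_length(sel2$order, 1L)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(49)
  p <- runif(20)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
})
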