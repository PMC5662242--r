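# P(child dosage | parent dosages) under Mendelian segregation
.mendel <- function(gc, gm, gf) {
  gam <- function(g) switch(as.character(g),
                            "0" = c(1, 0), "1" = c(0.5, 0.5), "2" = c(0, 1))
  pm <- gam(gm); pf <- gam(gf)
  # child alt dosage = maternal allele + paternal allele
  sum(vapply(0:1, function(am) sum(vapply(0:1, function(af)
    if (am + af == gc) pm[am + 1] * pf[af + 1] else 0, 0)), 0))
}

# full-sib pair genotype probability by enumeration over the parental
# mating table (independent of the k-coefficient expansion)
fsPairOracle <- function(gi, gj, p) {
  pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  tot <- 0
  for (gm in 0:2) for (gf in 0:2)
    tot <- tot + pg[gm + 1] * pg[gf + 1] *
      .mendel(gi, gm, gf) * .mendel(gj, gm, gf)
  tot
}

test_that("category thresholds are the midpoints of expected kinships", {
  th <- deriveKinshipThresholds()
  expect_equal(unname(th["full-sib/half-sib"]), 0.1875)
  expect_equal(unname(th["half-sib/first-cousin"]), 0.09375)
  cats <- kinshipCategories()
  expect_equal(cats$k0 + cats$k1 + cats$k2, rep(1, nrow(cats)))
  expect_equal(cats$expectedKinship[cats$name == "full-sib"], 0.25)
  expect_equal(cats$expectedKinship[cats$name == "half-sib"], 0.125)
  expect_length(deriveKinshipThresholds(cats[1, ]), 0)
  expect_error(deriveKinshipThresholds(cats[nrow(cats):1, ]), "ordered")
})

test_that("pairs are classified by the threshold rules with site metadata attached", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.203    # full-sib
  m["a", "c"] <- m["c", "a"] <- 0.156    # half-sib
  m["a", "d"] <- m["d", "a"] <- 0.05     # unrelated
  sites <- c(a = "S1", b = "S2", c = "S1", d = "S1")
  xy <- cbind(x = c(0, 3657, 10, 20), y = c(0, 0, 0, 0))
  rownames(xy) <- letters[1:4]
  calls <- classifyKinshipPairs(PairwiseMatrix(m, "kinship"),
                                siteMap = sites, coords = xy)
  get <- function(i, j) calls[calls$i == i & calls$j == j, ]
  expect_equal(get("a", "b")$category, "full-sib")
  expect_false(get("a", "b")$sameSite)
  expect_equal(get("a", "b")$separation, 3657)
  expect_equal(get("a", "c")$category, "half-sib")
  expect_equal(get("a", "d")$category, "unrelated")
})

test_that("full-sib pruning keeps the least-missing member per component", {
  calls <- data.frame(i = c("A", "B", "D"), j = c("B", "C", "E"),
                      k = 0.25, category = "full-sib")
  calls$category[3] <- "full-sib"
  miss <- c(A = 0.05, B = 0.02, C = 0.10, D = 0.01, E = 0.02, F = 0)
  kept <- pruneFullSibGroups(calls, miss, LETTERS[1:6])
  expect_setequal(kept, c("B", "D", "F"))
  # two disjoint FS pairs leave two representatives
  calls2 <- data.frame(i = c("A", "C"), j = c("B", "D"), k = 0.3,
                       category = "full-sib")
  expect_length(pruneFullSibGroups(calls2, miss, LETTERS[1:4]), 2L)
})

test_that("pruning arithmetic matches component counts on a sampling-scale fixture", {
  # 152 individuals, 36 of them spread over 12 full-sib components of 3
  ped <- generatePedigreeFixture(nFamilies = 12, familySizes = 3,
                                 nUnrelated = 152 - 36, nLoci = 50,
                                 missingRate = 0.05, seed = 21)
  tr <- ped$truth
  expect_equal(nrow(tr), 152L)
  nInComp <- sum(tr$type == "full-sib-family")
  expect_equal(nInComp, 36L)
  # sibship graph taken from the pedigree truth
  fs <- tr[tr$type == "full-sib-family", ]
  edges <- do.call(rbind, lapply(split(fs$id, fs$family), function(ids)
    data.frame(t(combn(ids, 2)))))
  calls <- data.frame(i = edges[, 1], j = edges[, 2], k = 0.25,
                      category = "full-sib")
  kept <- pruneFullSibGroups(calls, missingnessOf(ped$genotypes),
                             individualIds(ped$genotypes))
  nComp <- 12L
  expect_equal(length(kept), 152L - (nInComp - nComp))
  # every component's survivor is its least-missing member
  miss <- missingnessOf(ped$genotypes)
  for (fam in unique(fs$family)) {
    ids <- fs$id[fs$family == fam]
    surv <- intersect(kept, ids)
    expect_length(surv, 1L)
    expect_equal(min(miss[ids]), unname(miss[surv]))
  }
})

test_that("pair-genotype likelihoods are proper and obey independence and exclusion", {
  cats <- kinshipCategories()
  for (nm in cats$name) {
    for (p in c(0.1, 0.3, 0.5, 0.7)) {
      tot <- sum(vapply(0:2, function(a) sum(vapply(0:2, function(b)
        exp(relationshipLogLik(a, b, nm, p)), 0)), 0))
      expect_equal(tot, 1, tolerance = 1e-9,
                   label = paste("properness", nm, p))
    }
  }
  # unrelated: product of marginal Hardy-Weinberg probabilities
  p <- 0.3; pg <- c(0.49, 0.42, 0.09)
  expect_equal(relationshipLogLik(1, 2, "unrelated", p),
               log(pg[2] * pg[3]), tolerance = 1e-12)
  # parent-offspring with opposite homozygotes is impossible
  expect_equal(relationshipLogLik(0, 2, "parent-offspring", 0.5), -Inf)
})

test_that("full-sib likelihood matches the parental mating-table enumeration", {
  for (p in c(0.2, 0.5, 0.8)) {
    for (pair in list(c(1, 1), c(0, 0), c(2, 0), c(1, 2))) {
      expect_equal(exp(relationshipLogLik(pair[1], pair[2], "full-sib", p)),
                   fsPairOracle(pair[1], pair[2], p), tolerance = 1e-12,
                   label = paste("fs", p, pair[1], pair[2]))
    }
  }
})

test_that("relationship hypothesis tests distinguish true full sibs from half sibs", {
  set.seed(22)
  nRep <- 25
  freqs <- runif(300, 0.2, 0.8)
  drawPair <- function(shareBoth) {
    mo <- rbind(rbinom(300, 1, freqs), rbinom(300, 1, freqs))
    fa1 <- rbind(rbinom(300, 1, freqs), rbinom(300, 1, freqs))
    fa2 <- if (shareBoth) fa1
           else rbind(rbinom(300, 1, freqs), rbinom(300, 1, freqs))
    ch <- function(m, f) m[cbind(sample(1:2, 300, TRUE), 1:300)] +
      f[cbind(sample(1:2, 300, TRUE), 1:300)]
    list(gi = ch(mo, fa1), gj = ch(mo, fa2))
  }
  pFs <- vapply(seq_len(nRep), function(r) {
    pr <- drawPair(TRUE)
    relationshipTest(pr$gi, pr$gj, "full-sib", "half-sib", freqs,
                     nSims = 2000, seed = r)$p
  }, 0)
  expect_gte(mean(pFs < 0.05), 0.8)
  pHs <- vapply(seq_len(nRep), function(r) {
    pr <- drawPair(FALSE)
    relationshipTest(pr$gi, pr$gj, "full-sib", "half-sib", freqs,
                     nSims = 2000, seed = 1000 + r)$p
  }, 0)
  expect_gte(mean(pHs > 0.05), 0.8)
  # under the alternative truth, p-values are roughly uniform
  ks <- suppressWarnings(stats::ks.test(pHs, "punif"))
  expect_gt(ks$p.value, 0.005)
})

test_that("testing a category against itself gives a null log-likelihood ratio", {
  set.seed(23)
  freqs <- runif(100, 0.2, 0.8)
  gi <- rbinom(100, 2, freqs); gj <- rbinom(100, 2, freqs)
  res <- relationshipTest(gi, gj, "half-sib", "half-sib", freqs,
                          nSims = 500, seed = 1)
  expect_equal(res$lr, 0)
  expect_gt(res$p, 0.4)
})
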