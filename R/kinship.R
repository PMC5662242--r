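#' Standard relationship categories and their IBD-sharing coefficients
#'
#' Each category carries the probabilities (k0, k1, k2) that a pair shares
#' 0, 1 or 2 alleles identical by descent at a locus; the expected kinship
#' coefficient is k1/4 + k2/2. The first-cousin row exists only to anchor
#' the lower half-sibling boundary.
#'
#' @return data.frame with columns `name`, `k0`, `k1`, `k2`,
#'   `expectedKinship`, ordered by decreasing expected kinship
#' @export
kinshipCategories <- function() {
  d <- data.frame(
    name = c("parent-offspring", "full-sib", "half-sib", "first-cousin",
             "unrelated"),
    k0 = c(0, 0.25, 0.5, 0.75, 1),
    k1 = c(1, 0.5, 0.5, 0.25, 0),
    k2 = c(0, 0.25, 0, 0, 0))
  d$expectedKinship <- d$k1 / 4 + d$k2 / 2
  d[order(-d$expectedKinship), ]
}

#' Midpoint thresholds between adjacent kinship categories
#'
#' Assigning each pair to its most likely category by kinship value places
#' each decision boundary at the midpoint of the adjacent categories'
#' expected kinship: the full-sib/half-sib boundary is
#' (0.25 + 0.125)/2 = 0.1875 and the half-sib/first-cousin boundary
#' (0.125 + 0.0625)/2 = 0.09375.
#'
#' @param categories data.frame as from [kinshipCategories()] with at least
#'   `name` and `expectedKinship`
#' @return named numeric of boundaries between successive categories;
#'   empty for a single category
#' @export
deriveKinshipThresholds <- function(categories = kinshipCategories()) {
  ek <- categories$expectedKinship
  if (is.unsorted(rev(ek))) stop("categories must be ordered by decreasing expected kinship")
  if (nrow(categories) < 2) return(setNames(numeric(0), character(0)))
  mids <- (ek[-1] + ek[-length(ek)]) / 2
  setNames(mids, paste(categories$name[-length(ek)],
                       categories$name[-1], sep = "/"))
}

#' Classify pairs of individuals from their kinship values
#'
#' Pairs with k strictly above `fsThreshold` are called full siblings;
#' pairs with `hsThreshold < k <= fsThreshold` half siblings; the rest
#' unrelated. Site membership and geographic separation are attached when
#' the kinship matrix came from a [GenotypeMatrix-class] with metadata.
#'
#' @param k a [PairwiseMatrix-class] of kind `"kinship"`
#' @param fsThreshold full-sib boundary (default 0.1875)
#' @param hsThreshold half-sib boundary (default 0.09375)
#' @param siteMap optional named vector individual -> site
#' @param coords optional matrix of individual coordinates (m)
#' @return data.frame with one row per unordered pair: `i`, `j`, `k`,
#'   `category`, `sameSite`, `separation`
#' @export
classifyKinshipPairs <- function(k, fsThreshold = 0.1875,
                                 hsThreshold = 0.09375,
                                 siteMap = NULL, coords = NULL) {
  stopifnot(fsThreshold > hsThreshold, hsThreshold > 0)
  m <- as.matrix(k)
  labs <- rownames(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  kv <- m[upper.tri(m)]
  cat <- ifelse(kv > fsThreshold, "full-sib",
                ifelse(kv > hsThreshold, "half-sib", "unrelated"))
  out <- data.frame(i = labs[ut[, 1]], j = labs[ut[, 2]], k = kv,
                    category = cat, stringsAsFactors = FALSE)
  if (!is.null(siteMap))
    out$sameSite <- siteMap[out$i] == siteMap[out$j]
  if (!is.null(coords)) {
    dx <- coords[out$i, 1] - coords[out$j, 1]
    dy <- coords[out$i, 2] - coords[out$j, 2]
    out$separation <- sqrt(dx^2 + dy^2)
  }
  out
}

#' Prune full-sibling groups to a single representative
#'
#' Builds a graph whose edges are the full-sib pairs, takes connected
#' components (putative full-sibling groups) and keeps, per component, the
#' member with the smallest missing-data fraction (ties broken by
#' lexicographic id). Individuals outside any full-sib component are all
#' retained.
#'
#' @param calls data.frame from [classifyKinshipPairs()]
#' @param missingness named per-individual missing fraction (see
#'   [missingnessOf()]); individuals absent from the vector are treated as
#'   complete
#' @param ids the full set of individual ids under consideration
#' @return character vector of retained ids (original order)
#' @export
pruneFullSibGroups <- function(calls, missingness, ids) {
  fs <- calls[calls$category == "full-sib", , drop = FALSE]
  if (!nrow(fs)) return(ids)
  g <- igraph::graph_from_data_frame(fs[, c("i", "j")], directed = FALSE,
                                     vertices = unique(c(fs$i, fs$j)))
  comps <- igraph::components(g)
  drop <- character(0)
  for (cc in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == cc]
    miss <- missingness[members]
    miss[is.na(miss)] <- 0
    members <- members[order(miss, members)]
    drop <- c(drop, members[-1])
  }
  setdiff(ids, drop)
}

# P(unordered genotype pair | category k coefficients, alt allele freq p).
# Enumerates ordered allele pairs: under k2 the pair is genotype-identical,
# under k1 one allele of j is copied from a uniformly chosen allele of i and
# the other drawn from the population, under k0 both individuals are
# independent Hardy-Weinberg draws.
.pairGenotypeProb <- function(gi, gj, p, k) {
  q <- 1 - p
  pg <- c(q^2, 2 * p * q, p^2)           # P(g) for dosages 0,1,2
  p0 <- pg[gi + 1] * pg[gj + 1]
  p2 <- pg[gi + 1] * (gi == gj)
  # one-allele-IBD transition: j receives one allele from i, one from pop
  trans <- function(gi, gj) {
    s <- 0
    for (sh in 0:1) {                    # allele value shared (0=ref,1=alt)
      wSh <- if (gi == 1) 0.5 else if ((gi == 2) == (sh == 1)) 1 else 0
      if (wSh == 0) next
      for (oth in 0:1) {
        wOth <- if (oth == 1) p else q
        if (sh + oth == gj) s <- s + wSh * wOth
      }
    }
    s
  }
  p1 <- pg[gi + 1] * trans(gi, gj)
  k[1] * p0 + k[2] * p1 + k[3] * p2
}

#' Log-likelihood of a pair's genotypes under a relationship category
#'
#' Product over loci of \eqn{\sum_m k_m P(g_i, g_j \mid m)} where \eqn{m}
#' counts alleles shared identical by descent and genotype probabilities
#' follow Hardy-Weinberg at the panel allele frequencies. Loci missing in
#' either member are skipped. A Mendelian-impossible configuration under a
#' category with the corresponding k = 0 yields `-Inf`.
#'
#' @param gi,gj dosage vectors (0/1/2/NA) over the same loci
#' @param category one row of [kinshipCategories()] (or its `name`)
#' @param freqs data.frame with `altFreq` per locus ([alleleFrequencies()])
#' @export
relationshipLogLik <- function(gi, gj, category, freqs) {
  k <- .resolveCategory(category)
  p <- if (is.data.frame(freqs)) freqs$altFreq else freqs
  use <- !is.na(gi) & !is.na(gj) & !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no shared informative locus")
  ll <- 0
  for (l in which(use)) {
    pr <- .pairGenotypeProb(gi[l], gj[l], p[l], k)
    ll <- ll + log(pr)
  }
  ll
}

.resolveCategory <- function(category) {
  if (is.character(category)) {
    cats <- kinshipCategories()
    row <- cats[cats$name == category, ]
    if (!nrow(row)) stop("unknown category: ", category)
    category <- row
  }
  c(category$k0, category$k1, category$k2)
}

# 3x3 per-locus log-likelihood lookup tables for a category
.pairProbTable <- function(p, k) {
  outer(0:2, 0:2, Vectorize(function(a, b) .pairGenotypeProb(a, b, p, k)))
}

#' Simulation-based hypothesis test of a putative relationship
#'
#' The observed statistic is the log-likelihood ratio
#' logL(putative) - logL(alternative) for the pair. The null distribution
#' is built from `nSims` genotype pairs simulated under the *alternative*
#' category at the panel allele frequencies; the p-value is the plus-one
#' corrected proportion of simulated ratios at least as large as observed.
#' A small p rejects the alternative in favour of the putative category.
#'
#' @param gi,gj dosage vectors of the pair
#' @param putative,alternative category names or rows of
#'   [kinshipCategories()]
#' @param freqs data.frame with `altFreq` per locus
#' @param nSims number of simulated pairs (>= 100; default 100000)
#' @param seed optional RNG seed
#' @return list with `lr`, `p`, `nSims`, `putative`, `alternative`
#' @export
relationshipTest <- function(gi, gj, putative, alternative, freqs,
                             nSims = 100000L, seed = NULL) {
  stopifnot(nSims >= 100)
  if (!is.null(seed)) set.seed(seed)
  kP <- .resolveCategory(putative)
  kA <- .resolveCategory(alternative)
  p <- if (is.data.frame(freqs)) freqs$altFreq else freqs
  use <- !is.na(gi) & !is.na(gj) & !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("monomorphic or empty panel: test powerless")
  p <- p[use]; gi <- gi[use]; gj <- gj[use]
  L <- length(p)
  tabP <- lapply(p, .pairProbTable, k = kP)
  tabA <- lapply(p, .pairProbTable, k = kA)
  lrTab <- lapply(seq_len(L), function(l) log(tabP[[l]]) - log(tabA[[l]]))
  obs <- sum(vapply(seq_len(L),
                    function(l) lrTab[[l]][gi[l] + 1, gj[l] + 1], 0))
  # simulate pairs under the alternative, locus-wise
  lr <- numeric(nSims)
  for (l in seq_len(L)) {
    probs <- as.vector(tabA[[l]])                # 9 ordered combos
    draw <- sample.int(9L, nSims, replace = TRUE, prob = probs)
    lr <- lr + lrTab[[l]][draw]
  }
  pval <- (sum(lr >= obs - 1e-12) + 1) / (nSims + 1)
  list(lr = obs, p = pval, nSims = as.integer(nSims),
       putative = if (is.character(putative)) putative else putative$name,
       alternative = if (is.character(alternative)) alternative
                     else alternative$name)
}
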