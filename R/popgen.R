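#' Per-locus allele frequencies from non-missing calls
#'
#' @param g a [GenotypeMatrix-class]
#' @return data.frame with one row per locus: `altFreq`, `refFreq`, `n`
#'   (number of sampled gene copies, i.e. 2 x called individuals)
#' @export
alleleFrequencies <- function(g) {
  st <- .lociStats(g)
  data.frame(altFreq = st$altFreq, refFreq = 1 - st$altFreq,
             n = 2L * st$nCalled, row.names = rownames(g))
}

#' Loiselle kinship coefficients between all pairs of individuals
#'
#' Multilocus kinship of Loiselle et al.: per locus and allele the numerator
#' is \eqn{(p_i - \bar p)(p_j - \bar p) + \bar p(1-\bar p)/(n-1)}, where
#' \eqn{p_i \in \{0, 1/2, 1\}} is the allele frequency within individual
#' \eqn{i}, \eqn{\bar p} the sample frequency over all non-missing calls and
#' \eqn{n} the number of sampled gene copies at the locus; the denominator is
#' \eqn{\bar p(1-\bar p)}. Numerator and denominator are summed over alleles
#' and over the loci called in both pair members before the ratio is taken
#' (ratio-of-sums weighting, the convention of multilocus kinship software).
#' Expected values are about 0.25 for full siblings, 0.125 for half
#' siblings and 0 for unrelated individuals.
#'
#' Pairs sharing no called locus get `NA` with a warning.
#'
#' @param g a [GenotypeMatrix-class] with >= 2 individuals
#' @return a [PairwiseMatrix-class] of kind `"kinship"` (diagonal 0)
#' @export
loiselleKinship <- function(g) {
  X <- dosageMatrix(g)
  stopifnot(nrow(X) >= 2)
  st <- .lociStats(g)
  pbar <- st$altFreq
  n <- 2 * st$nCalled
  use <- !is.na(pbar) & pbar > 0 & pbar < 1 & n > 2
  X <- X[, use, drop = FALSE]
  pbar <- pbar[use]; n <- n[use]
  if (!ncol(X)) stop("no polymorphic loci available")
  M <- !is.na(X)                                # called mask
  Z <- X / 2 - matrix(pbar, nrow(X), ncol(X), byrow = TRUE)
  Z[!M] <- 0
  Mn <- M * 1
  pq <- pbar * (1 - pbar)
  num <- Z %*% t(Z) + Mn %*% (t(Mn) * (pq / (n - 1)))
  den <- Mn %*% (t(Mn) * pq)
  k <- num / den
  if (any(den == 0)) {
    warning("pair(s) with no shared called locus: kinship undefined")
    k[den == 0] <- NA_real_
  }
  diag(k) <- 0
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(X), rownames(X))
  PairwiseMatrix(k, kind = "kinship")
}

#' Rousset's a: genetic distance between individuals
#'
#' Individual-level analogue of \eqn{F_{ST}/(1-F_{ST})}, built from gene
#' identity probabilities: per locus, \eqn{\hat Q_w} is the sample-average
#' probability of identity of the two gene copies within an individual
#' (1 - observed heterozygosity) and \eqn{\hat Q_{ij}} the probability of
#' identity between a random gene copy of \eqn{i} and one of \eqn{j}. The
#' pairwise statistic is the ratio of sums over the loci called in both pair
#' members, \eqn{\hat a_{ij} = \sum_l (\hat Q_{w,l} - \hat Q_{ij,l}) /
#' \sum_l (1 - \hat Q_{w,l})}. Under two-dimensional isolation by distance
#' its regression on log geographic distance is positive.
#'
#' When the denominator vanishes (no within-individual heterozygosity on
#' the shared loci) the value is 0 if the numerator also vanishes and `NA`
#' (flagged with a warning) otherwise.
#'
#' @param g a [GenotypeMatrix-class] with >= 2 individuals
#' @return a [PairwiseMatrix-class] of kind `"genetic-distance"`
#' @export
roussetA <- function(g) {
  X <- dosageMatrix(g)
  stopifnot(nrow(X) >= 2)
  a <- X / 2                               # within-individual alt frequency
  M <- !is.na(X)
  qw <- colSums((X == 0 | X == 2) & M, na.rm = TRUE) / colSums(M)
  # Q_ij per locus = a_i a_j + (1-a_i)(1-a_j); accumulate masked sums
  A <- a; A[!M] <- 0
  B <- 1 - a; B[!M] <- 0
  Mn <- M * 1
  Qsum <- A %*% t(A) + B %*% t(B)
  numW <- Mn %*% (t(Mn) * qw)              # sum over shared loci of Q_w
  nShared <- Mn %*% t(Mn)
  den <- nShared - numW                    # sum of (1 - Q_w)
  num <- numW - Qsum
  out <- num / den
  zero <- den == 0
  if (any(zero)) {
    out[zero & abs(num) < 1e-12] <- 0
    und <- zero & abs(num) >= 1e-12
    if (any(und)) {
      warning("pair(s) with undefined Rousset's a flagged NA")
      out[und] <- NA_real_
    }
  }
  diag(out) <- 0
  out <- (out + t(out)) / 2
  dimnames(out) <- list(rownames(X), rownames(X))
  PairwiseMatrix(out, kind = "genetic-distance")
}

#' Nei's standard genetic distance between groups
#'
#' \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})} where \eqn{J_x}, \eqn{J_y} and
#' \eqn{J_{xy}} are the within- and between-group gene identities
#' (\eqn{\sum_a p_a^2} and \eqn{\sum_a p_{x,a} p_{y,a}}) averaged over the
#' loci with calls in both groups. With `unbiased = TRUE` the within-group
#' identities use the small-sample correction
#' \eqn{(2n \sum p^2 - 1)/(2n - 1)}.
#'
#' @param g a [GenotypeMatrix-class]
#' @param grouping optional named vector individual -> group; defaults to
#'   site membership
#' @param unbiased use the unbiased within-group identities (default FALSE)
#' @return a [PairwiseMatrix-class] of kind `"genetic-distance"` at group
#'   level; fixed opposite alleles give `Inf` with a warning
#' @export
neiD <- function(g, grouping = siteOf(g), unbiased = FALSE) {
  X <- dosageMatrix(g)
  grouping <- grouping[rownames(X)]
  groups <- unique(grouping)
  L <- ncol(X)
  pMat <- matrix(NA_real_, length(groups), L,
                 dimnames = list(groups, colnames(X)))
  nMat <- matrix(0, length(groups), L, dimnames = dimnames(pMat))
  for (gr in groups) {
    xs <- X[grouping == gr, , drop = FALSE]
    nCalled <- colSums(!is.na(xs))
    pMat[gr, ] <- ifelse(nCalled > 0,
                         colSums(xs, na.rm = TRUE) / (2 * nCalled), NA)
    nMat[gr, ] <- nCalled
  }
  J <- function(p, q) p * q + (1 - p) * (1 - q)
  Jw <- function(p, n) {
    j <- p^2 + (1 - p)^2
    if (unbiased) (2 * n * j - 1) / (2 * n - 1) else j
  }
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    shared <- !is.na(pMat[i, ]) & !is.na(pMat[j, ])
    if (!any(shared)) stop("groups ", groups[i], " and ", groups[j],
                           " share no called locus")
    Jx <- mean(Jw(pMat[i, shared], nMat[i, shared]))
    Jy <- mean(Jw(pMat[j, shared], nMat[j, shared]))
    Jxy <- mean(J(pMat[i, shared], pMat[j, shared]))
    if (Jxy <= 0) {
      warning("zero between-group identity: infinite distance flagged")
      D[i, j] <- D[j, i] <- Inf
    } else D[i, j] <- D[j, i] <- -log(Jxy / sqrt(Jx * Jy))
  }
  PairwiseMatrix(D, kind = "genetic-distance")
}

#' One-level AMOVA from a pairwise distance matrix
#'
#' Partitions the total sum of squared pairwise distances into among- and
#' within-group components: \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}, and
#' \eqn{SS_{among} = SS_{total} - SS_{within}}. The effect size is reported
#' as \eqn{\eta^2 = SS_{among}/SS_{total}} and significance by permuting
#' group labels (plus-one corrected p on the pseudo-F statistic).
#'
#' @param distances a [PairwiseMatrix-class] of distances
#' @param grouping named vector label -> group (>= 1 per group)
#' @param nPerm permutations (default 999)
#' @param seed optional RNG seed
#' @return an [AmovaResult-class]
#' @export
amova <- function(distances, grouping, nPerm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d2 <- as.matrix(distances)^2
  labs <- rownames(d2)
  grouping <- grouping[labs]
  if (anyNA(grouping)) stop("grouping missing for some labels")
  groups <- unique(grouping)
  if (any(table(grouping) == 0)) stop("empty group")
  n <- length(labs)
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssw <- function(gr) {
    s <- 0
    for (gg in unique(gr)) {
      idx <- which(gr == gg)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  ssWithin <- ssw(grouping)
  ssAmong <- ssTotal - ssWithin
  dfA <- length(groups) - 1
  dfW <- n - length(groups)
  stat <- if (dfA > 0 && ssWithin > 0) (ssAmong / dfA) / (ssWithin / dfW)
          else 0
  # variance components (Excoffier): n0-weighted
  sizes <- table(grouping)[groups]
  n0 <- if (dfA > 0) (n - sum(sizes^2) / n) / dfA else n
  sigW <- if (dfW > 0) ssWithin / dfW else 0
  sigA <- if (dfA > 0) max(0, (ssAmong / dfA - sigW) / n0) else 0
  p <- NA_real_
  if (dfA > 0 && nPerm > 0) {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      grPerm <- sample(grouping)
      sswP <- ssw(grPerm)
      statP <- ((ssTotal - sswP) / dfA) / (sswP / dfW)
      if (statP >= stat - 1e-12) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (nPerm + 1)
  }
  new("AmovaResult", ssAmong = ssAmong, ssWithin = ssWithin,
      ssTotal = ssTotal, dfAmong = dfA, dfWithin = dfW,
      sigmaAmong = sigA, sigmaWithin = sigW,
      etaSq = if (ssTotal > 0) ssAmong / ssTotal else 0,
      statistic = stat, p = p, nPerm = as.integer(nPerm))
}

setMethod("show", "AmovaResult", function(object) {
  cat("One-level AMOVA (", object@nPerm, "permutations )\n")
  cat(sprintf("  SS among  = %.4g (df %d)\n", object@ssAmong,
              as.integer(object@dfAmong)))
  cat(sprintf("  SS within = %.4g (df %d)\n", object@ssWithin,
              as.integer(object@dfWithin)))
  cat(sprintf("  eta^2 = %.4f   pseudo-F = %.3f   P = %.4g\n",
              object@etaSq, object@statistic, object@p))
})

#' Effective number of alleles (Kimura-Crow)
#'
#' Per locus \eqn{n_e = 1/\sum_a p_a^2}; the return value is the total over
#' loci. A monomorphic locus contributes 1; a biallelic locus at p = 0.5
#' contributes 2 (the biallelic maximum).
#'
#' @param freqs data.frame as returned by [alleleFrequencies()] (columns
#'   `altFreq`, `refFreq`), or a numeric vector of alternate-allele
#'   frequencies
#' @export
effectiveAlleles <- function(freqs) {
  p <- if (is.data.frame(freqs)) freqs$altFreq else freqs
  p <- p[!is.na(p)]
  sum(1 / (p^2 + (1 - p)^2))
}

#' Loci needed to match an effective-allele count at maximum diversity
#'
#' A biallelic locus at maximum diversity has exactly 2 effective alleles,
#' so the matching locus count is `targetNe / 2`, rounded half-up to the
#' nearest integer (3694 effective alleles correspond to 1847 loci).
#'
#' @param targetNe target total effective-allele count (>= 0)
#' @export
lociForEffectiveAlleles <- function(targetNe) {
  stopifnot(targetNe >= 0)
  as.integer(floor(targetNe / 2 + 0.5))    # half-up
}
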