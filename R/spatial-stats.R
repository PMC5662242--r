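#' Mantel test between two pairwise matrices
#'
#' The statistic is the Pearson correlation between the strictly-upper
#' triangles; the null distribution is obtained by simultaneous row/column
#' permutation of the second matrix. The p-value is one-tailed (greater)
#' with plus-one correction. Cells that are `NA` in either matrix are
#' excluded pairwise.
#'
#' @param A,B [PairwiseMatrix-class] objects over the same labels
#' @param nPerm permutations (>= 99, default 999)
#' @param seed optional RNG seed
#' @return a [MantelResult-class]
#' @export
mantelTest <- function(A, B, nPerm = 999L, seed = NULL) {
  stopifnot(nPerm >= 99)
  if (!is.null(seed)) set.seed(seed)
  al <- .alignPairwise(A, B)
  a <- al[[1]]; b <- al[[2]]
  ut <- upper.tri(a)
  r <- .mantelR(a[ut], b[ut])
  n <- nrow(a)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    pidx <- sample.int(n)
    rp <- .mantelR(a[ut], b[pidx, pidx][ut])
    if (rp >= r - 1e-12) exceed <- exceed + 1L
  }
  new("MantelResult", r = r, p = (exceed + 1) / (nPerm + 1),
      nPerm = as.integer(nPerm), tail = "greater", kind = "mantel")
}

.mantelR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant matrix: Mantel correlation undefined")
  cor(x, y)
}

#' Partial Mantel test (effect of B on A with C removed)
#'
#' Both A and B are residualised on C by ordinary least squares over the
#' off-diagonal entries; the statistic is the Mantel correlation of the two
#' residual matrices. The null permutes the residual matrix of A by
#' simultaneous row/column permutation (residual-permutation scheme), which
#' respects the conditioning structure. A constant C reduces to the plain
#' Mantel test with a warning.
#'
#' @inheritParams mantelTest
#' @param C conditioning [PairwiseMatrix-class] (typically geographic
#'   distance)
#' @export
partialMantelTest <- function(A, B, C, nPerm = 999L, seed = NULL) {
  stopifnot(nPerm >= 99)
  if (!is.null(seed)) set.seed(seed)
  al <- .alignPairwise(A, B, C)
  a <- al[[1]]; b <- al[[2]]; cc <- al[[3]]
  ut <- upper.tri(a)
  if (sd(cc[ut], na.rm = TRUE) == 0) {
    warning("constant conditioning matrix: plain Mantel test returned")
    res <- mantelTest(A, B, nPerm = nPerm)
    return(new("MantelResult", r = res@r, p = res@p, nPerm = res@nPerm,
               tail = "greater", kind = "partial-mantel"))
  }
  residMat <- function(m) {
    v <- m[ut]; x <- cc[ut]
    ok <- is.finite(v) & is.finite(x)
    r <- rep(NA_real_, length(v))
    fit <- lm.fit(cbind(1, x[ok]), v[ok])
    r[ok] <- fit$residuals
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    out[ut] <- r
    out <- out + t(out)
    out
  }
  ra <- residMat(a); rb <- residMat(b)
  if (sd(ra[ut], na.rm = TRUE) < 1e-12 || sd(rb[ut], na.rm = TRUE) < 1e-12) {
    # degenerate: a matrix is an affine function of the conditioning matrix
    warning("constant residual matrix: partial correlation undefined, 0 returned")
    return(new("MantelResult", r = 0, p = 1, nPerm = as.integer(nPerm),
               tail = "greater", kind = "partial-mantel"))
  }
  r <- .mantelR(ra[ut], rb[ut])
  n <- nrow(a)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    pidx <- sample.int(n)
    rp <- .mantelR(ra[pidx, pidx][ut], rb[ut])
    if (rp >= r - 1e-12) exceed <- exceed + 1L
  }
  new("MantelResult", r = r, p = (exceed + 1) / (nPerm + 1),
      nPerm = as.integer(nPerm), tail = "greater",
      kind = "partial-mantel")
}

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("%s: r = %.4f, P = %.4g (%d permutations, tail %s)\n",
              object@kind, object@r, object@p, object@nPerm, object@tail))
})

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `p.adjust(..., method = "BH")` (step-up false
#' discovery rate control, monotone enforced).
#'
#' @param p vector of raw p-values in `[0, 1]`
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

# ---- PCNM ----------------------------------------------------------------

#' Principal coordinates of neighbour matrices (spatial eigenvectors)
#'
#' Delegates to [vegan::pcnm()]: the distance matrix is truncated at the
#' longest edge of its minimum spanning tree (entries above the threshold
#' replaced by four times the threshold), double-centred and
#' eigendecomposed; the positive-eigenvalue eigenvectors, rescaled to unit
#' norm, form the basis.
#'
#' @param D a [PairwiseMatrix-class] distance matrix (n >= 3)
#' @return a [PcnmBasis-class]
#' @export
pcnmBasis <- function(D) {
  m <- as.matrix(D)
  if (nrow(m) < 3) stop("PCNM needs at least 3 points")
  res <- vegan::pcnm(stats::as.dist(m))
  vec <- res$vectors                      # positive-eigenvalue axes only
  vals <- res$values[seq_len(ncol(vec))]
  keep <- vals > .Machine$double.eps^0.5 * max(vals)
  vec <- vec[, keep, drop = FALSE]
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")
  rownames(vec) <- rownames(m)
  new("PcnmBasis", vectors = vec, values = vals[keep],
      truncation = res$threshold)
}

# ---- distance-based redundancy analysis ----------------------------------

# PCoA embedding keeping non-negative eigenvalue axes (no correction);
# genetic distance matrices may be non-Euclidean, negative axes dropped.
.pcoaEmbed <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  # Gower double-centering: A - row means - column means + grand mean
  B <- sweep(A, 1, rowMeans(A))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  Y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  rownames(Y) <- rownames(D)
  Y
}

.asTermList <- function(x) {
  if (is.null(x) || (is.list(x) && !length(x))) return(list())
  if (is.data.frame(x)) x <- as.list(x)
  if (!is.list(x)) x <- list(term = x)
  lapply(x, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
}

#' Distance-based redundancy analysis with conditioning
#'
#' Embeds the response distance matrix by principal coordinates (keeping
#' positive-eigenvalue axes), residualises the embedding and the
#' explanatory terms on the conditional design, and projects the residual
#' embedding onto the explanatory design by ordinary least squares. The
#' inertia decomposition (conditional + constrained + unconstrained =
#' total) is exact. The model R-squared is the constrained fraction of the
#' inertia remaining after conditioning; the adjusted R-squared uses the
#' Ezekiel formula. Marginal significance of each term is assessed by
#' permutation of reduced-model residuals; effect sizes are reported as
#' eta-squared (marginal SS over total inertia) and collinearity as
#' variance inflation factors of the conditioned explanatory design.
#'
#' @param responseD [PairwiseMatrix-class] of response distances
#' @param explanatory named list of term matrices (columns are variables;
#'   a term may span several columns, e.g. two spatial eigenvectors)
#' @param conditional optional matrix of conditioning variables
#' @param nPerm permutations for the marginal tests (default 999)
#' @param seed optional RNG seed
#' @return an [OrdinationModel-class]
#' @export
fitDbrda <- function(responseD, explanatory = list(), conditional = NULL,
                     nPerm = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- .pcoaEmbed(as.matrix(responseD))
  n <- nrow(Y)
  total <- sum(Y^2)
  terms <- .asTermList(explanatory)
  qz <- NULL
  qcond <- 0L
  Yr <- Y
  if (!is.null(conditional) && length(conditional)) {
    Z <- as.matrix(conditional)
    qz <- qr(cbind(1, Z))
    qcond <- qz$rank - 1L
    Yr <- qr.resid(qz, Y)
  } else {
    Yr <- sweep(Y, 2, colMeans(Y))
  }
  ssCond <- total - sum(Yr^2)
  resTerm <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    if (!is.null(qz)) qr.resid(qz, M) else M
  }
  terms <- lapply(terms, resTerm)
  if (!length(terms)) {
    return(new("OrdinationModel", totalInertia = total,
               conditionalInertia = ssCond, constrainedInertia = 0,
               unconstrainedInertia = sum(Yr^2), r2 = 0, adjR2 = 0,
               terms = data.frame(term = character(0)),
               vif = numeric(0), nPerm = as.integer(nPerm),
               n = as.integer(n)))
  }
  X <- do.call(cbind, terms)
  colnames(X) <- unlist(mapply(function(nm, m)
    if (ncol(m) == 1) nm else paste0(nm, ".", seq_len(ncol(m))),
    names(terms), terms, SIMPLIFY = FALSE))
  termOfCol <- rep(names(terms), vapply(terms, ncol, 0L))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keepIdx <- sort(qx$pivot[seq_len(qx$rank)])
    warning("rank-deficient explanatory design; aliased columns dropped: ",
            paste(colnames(X)[-keepIdx], collapse = ", "))
    X <- X[, keepIdx, drop = FALSE]
    termOfCol <- termOfCol[keepIdx]
    terms <- terms[unique(termOfCol)]
    qx <- qr(X)
  }
  ssFit <- function(Q, M) sum(qr.fitted(Q, M)^2)
  ssConstr <- ssFit(qx, Yr)
  ssResid <- sum(Yr^2) - ssConstr
  m <- qx$rank
  dfResid <- n - 1 - qcond - m
  r2 <- ssConstr / (ssConstr + ssResid)
  adjR2 <- 1 - (1 - r2) * (n - qcond - 1) / (n - qcond - m - 1)
  # marginal tests: drop one term, permute residuals of the reduced model
  termCols <- split(seq_len(ncol(X)), factor(termOfCol, unique(termOfCol)))
  tt <- data.frame(term = names(termCols), df = NA_real_, ss = NA_real_,
                   etaSq = NA_real_, pseudoF = NA_real_, p = NA_real_)
  for (ti in seq_along(termCols)) {
    keepCols <- setdiff(seq_len(ncol(X)), termCols[[ti]])
    if (length(keepCols)) {
      qRed <- qr(X[, keepCols, drop = FALSE])
      ssRed <- ssFit(qRed, Yr)
      fitRed <- qr.fitted(qRed, Yr)
    } else {
      ssRed <- 0
      fitRed <- matrix(0, n, ncol(Yr))
    }
    residRed <- Yr - fitRed
    dfT <- length(termCols[[ti]])
    ssT <- ssConstr - ssRed
    Fobs <- (ssT / dfT) / (ssResid / dfResid)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      Yp <- fitRed + residRed[sample.int(n), , drop = FALSE]
      ssFull <- ssFit(qx, Yp)
      ssTp <- ssFull - ssFit(if (length(keepCols)) qRed else qx, Yp)
      if (!length(keepCols)) ssTp <- ssFull
      Fp <- (ssTp / dfT) / ((sum(Yp^2) - ssFull) / dfResid)
      if (Fp >= Fobs - 1e-12) exceed <- exceed + 1L
    }
    tt$df[ti] <- dfT
    tt$ss[ti] <- ssT
    tt$etaSq[ti] <- ssT / total
    tt$pseudoF[ti] <- Fobs
    tt$p[ti] <- (exceed + 1) / (nPerm + 1)
  }
  tt$pBH <- bhAdjust(tt$p)
  vif <- if (ncol(X) > 1) {
    R <- cor(X)
    setNames(diag(solve(R)), colnames(X))
  } else setNames(1, colnames(X))
  new("OrdinationModel", totalInertia = total, conditionalInertia = ssCond,
      constrainedInertia = ssConstr, unconstrainedInertia = ssResid,
      r2 = r2, adjR2 = adjR2, terms = tt, vif = vif,
      nPerm = as.integer(nPerm), n = as.integer(n))
}

#' @rdname OrdinationModel-class
#' @param x an OrdinationModel
#' @export
setMethod("termTable", "OrdinationModel", function(x) x@terms)

#' @rdname OrdinationModel-class
#' @export
setMethod("adjustedR2", "OrdinationModel", function(x) x@adjR2)

setMethod("show", "OrdinationModel", function(object) {
  cat("Distance-based RDA\n")
  cat(sprintf("  inertia: total %.4g = conditional %.4g + constrained %.4g + unconstrained %.4g\n",
              object@totalInertia, object@conditionalInertia,
              object@constrainedInertia, object@unconstrainedInertia))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f (%d permutations)\n",
              object@r2, object@adjR2, object@nPerm))
  if (nrow(object@terms)) print(object@terms, digits = 4)
})

#' Forward selection of dbRDA terms by adjusted R-squared
#'
#' Greedy construction: at each step the candidate whose addition yields
#' the largest adjusted R-squared is added; construction stops when no
#' candidate increases it. The accepted inclusion order is recorded, and
#' the final model is refitted with marginal permutation tests.
#'
#' @param responseD response distance [PairwiseMatrix-class]
#' @param candidates named list of candidate term matrices
#' @param conditional optional conditioning matrix
#' @param nPerm permutations for the final fit
#' @param seed optional RNG seed
#' @return list with `model` ([OrdinationModel-class]), `order` (accepted
#'   term names) and `path` (adjusted R-squared after each acceptance)
#' @export
forwardSelectDbrda <- function(responseD, candidates, conditional = NULL,
                               nPerm = 999L, seed = NULL) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  candidates <- .asTermList(candidates)
  chosen <- character(0)
  best <- 0                      # empty model: adjusted R2 defined as 0
  path <- numeric(0)
  repeat {
    remaining <- setdiff(names(candidates), chosen)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(nm) {
      m <- fitDbrda(responseD, candidates[c(chosen, nm)], conditional,
                    nPerm = 0L)
      m@adjR2
    }, numeric(1))
    if (max(scores) <= best + 1e-12) break
    pick <- remaining[which.max(scores)]
    chosen <- c(chosen, pick)
    best <- max(scores)
    path <- c(path, best)
  }
  model <- fitDbrda(responseD, candidates[chosen], conditional,
                    nPerm = nPerm, seed = seed)
  list(model = model, order = chosen, path = path)
}
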