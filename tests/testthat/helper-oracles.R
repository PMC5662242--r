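# brute-force Loiselle oracle: explicit sums over alleles and loci
loiselleOracle <- function(gm) {
  X <- dosageMatrix(gm)
  L <- ncol(X); n <- nrow(X)
  pb <- vapply(seq_len(L), function(l) mean(X[, l], na.rm = TRUE) / 2, 0)
  nn <- vapply(seq_len(L), function(l) 2 * sum(!is.na(X[, l])), 0)
  k <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- den <- 0
    for (l in seq_len(L)) {
      if (is.na(X[i, l]) || is.na(X[j, l])) next
      p <- pb[l]
      if (is.na(p) || p <= 0 || p >= 1 || nn[l] <= 2) next
      for (al in 0:1) {
        pi <- if (al) X[i, l] / 2 else 1 - X[i, l] / 2
        pj <- if (al) X[j, l] / 2 else 1 - X[j, l] / 2
        pa <- if (al) p else 1 - p
        num <- num + (pi - pa) * (pj - pa) + pa * (1 - pa) / (nn[l] - 1)
        den <- den + pa * (1 - pa)
      }
    }
    k[i, j] <- num / den
  }
  k
}

# identity-probability oracle for Rousset's a
roussetOracle <- function(gm) {
  X <- dosageMatrix(gm)
  L <- ncol(X); n <- nrow(X)
  qw <- vapply(seq_len(L), function(l) {
    v <- X[, l][!is.na(X[, l])]
    mean(v %in% c(0, 2))
  }, 0)
  a <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- den <- 0
    for (l in seq_len(L)) {
      if (is.na(X[i, l]) || is.na(X[j, l])) next
      ai <- X[i, l] / 2; aj <- X[j, l] / 2
      Qij <- ai * aj + (1 - ai) * (1 - aj)
      num <- num + qw[l] - Qij
      den <- den + 1 - qw[l]
    }
    a[i, j] <- if (den > 0) num / den else if (abs(num) < 1e-12) 0 else NA
  }
  a
}

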