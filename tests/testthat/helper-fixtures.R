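# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write into tempdir().

# quick GenotypeMatrix with widely spaced loci (thinning is a no-op)
makeGm <- function(calls, sites = NULL, x = NULL, y = NULL,
                   spacing = 1e6) {
  n <- nrow(calls); L <- ncol(calls)
  if (is.null(sites)) sites <- rep("S1", n)
  ids <- if (!is.null(rownames(calls))) rownames(calls)
         else sprintf("i%02d", seq_len(n))
  GenotypeMatrix(
    calls = calls,
    loci = data.frame(scaffold = "scafA", position = (seq_len(L) - 1) * spacing),
    samples = data.frame(id = ids, site = sites,
                         x = if (is.null(x)) NA_real_ else x,
                         y = if (is.null(y)) NA_real_ else y))
}

# minimal VCF writer used to exercise the reader; records is a data.frame
# with chrom, pos, ref, alt and gt (matrix of GT strings, one column per
# sample)
writeToyVcf <- function(path, records, gt, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# random genotypes in Hardy-Weinberg proportions at given alt frequencies
hweGenotypes <- function(n, freqs) {
  L <- length(freqs)
  matrix(rbinom(n * L, 2L, rep(freqs, each = n)), n, L)
}

# independent exact-HWE p-value oracle: enumerate every heterozygote count
# compatible with the allele counts, probability via choose()
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nm <- min(nA, 2 * n - nA)
  hs <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hs, function(h) {
    homMinor <- (nm - h) / 2
    homMajor <- n - h - homMinor
    exp(lfactorial(n) - lfactorial(homMajor) - lfactorial(h) -
          lfactorial(homMinor) + h * log(2) +
          lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-12)])
}

# the clustered multi-site sampling layout reused by the Type-I fixtures
siteLayout <- function(nSites = 10, perSite = 10, extent = c(0, 20000),
                       seed = 99) {
  set.seed(seed)
  ctr <- cbind(runif(nSites, extent[1] + 2000, extent[2] - 2000),
               runif(nSites, extent[1] + 2000, extent[2] - 2000))
  focal <- ctr[rep(seq_len(nSites), each = perSite), ] +
    matrix(rnorm(2 * nSites * perSite, 0, 150), nSites * perSite, 2)
  ids <- sprintf("i%03d", seq_len(nSites * perSite))
  rownames(focal) <- ids
  list(centres = ctr, focal = focal, ids = ids,
       sites = setNames(rep(paste0("S", seq_len(nSites)), each = perSite),
                        ids))
}
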