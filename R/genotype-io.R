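#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) with [vcfR::read.vcfR()] and
#' returns a [GenotypeMatrix-class] of alternate-allele dosages. Records that
#' are not biallelic SNPs (multiallelic ALT, indels, symbolic alleles) are
#' skipped and counted in a `"vcf-parse"` [FilterReport-class] attached to
#' the result. Genotypes `./.` (or any call containing `.`) map to `NA`.
#'
#' @param path VCF file
#' @param meta optional data.frame with columns `id`, `site`, `x`, `y`;
#'   matched to VCF sample names. Unmatched VCF samples raise an error.
#'   Without `meta`, all individuals are placed in one site `"S1"` with no
#'   coordinates.
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypeVcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  isSnp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  isSnp[is.na(isSnp)] <- FALSE
  nSkipped <- sum(!isSnp)
  if (nSkipped)
    message(nSkipped, " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[isSnp, , drop = FALSE]
  fix <- fix[isSnp, , drop = FALSE]
  alleles <- gsub("[|/]", "", gt)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[alleles == "00"] <- 0
  dos[alleles == "01" | alleles == "10"] <- 1
  dos[alleles == "11"] <- 2
  ids <- colnames(gt)
  if (is.null(meta)) {
    samples <- data.frame(id = ids, site = "S1", x = NA_real_, y = NA_real_)
  } else {
    idx <- match(ids, as.character(meta$id))
    if (anyNA(idx))
      stop("VCF samples missing from metadata: ",
           paste(ids[is.na(idx)], collapse = ", "))
    samples <- data.frame(id = ids, site = as.character(meta$site)[idx],
                          x = meta$x[idx], y = meta$y[idx])
  }
  gm <- GenotypeMatrix(
    calls = t(dos),
    loci = data.frame(scaffold = fix$CHROM, position = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT),
    samples = samples)
  .appendReport(gm, new("FilterReport", rule = "vcf-parse", axis = "locus",
                        nRemoved = as.integer(nSkipped),
                        nRetained = nrow(gm), params = list()))
}

#' Read sample metadata (id, site, x, y) from CSV
#' @param path CSV file with columns `id`, `site`, `x`, `y` (projected m)
#' @export
readSampleMetadata <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "site", "x", "y")
  if (!all(need %in% names(m)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  m
}

#' Exact test of Hardy-Weinberg equilibrium for one biallelic locus
#'
#' Conditional exact test on the genotype counts: the p-value is the summed
#' probability, over all heterozygote counts compatible with the observed
#' allele counts, of genotype configurations no more probable than the one
#' observed (no mid-p correction).
#'
#' @param nAA,nAa,naa genotype counts
#' @return two-sided exact p-value
#' @examples
#' hweExactTest(25, 50, 25)   # perfect proportions, p = 1
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(NA_real_)
  nA <- 2 * nAA + nAa
  nm <- min(nA, 2 * n - nA)                 # minor allele count
  hs <- seq(nm %% 2, nm, by = 2)            # feasible heterozygote counts
  logp <- vapply(hs, function(h) {
    homMinor <- (nm - h) / 2
    homMajor <- n - h - homMinor
    h * log(2) + lgamma(n + 1) -
      (lgamma(homMajor + 1) + lgamma(h + 1) + lgamma(homMinor + 1)) +
      lgamma(nm + 1) + lgamma(2 * n - nm + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(nAa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Remove individuals with excess missing data
#'
#' Individuals whose fraction of missing calls strictly exceeds
#' `maxMissing` are removed (an individual at exactly the threshold is
#' retained).
#'
#' @param g a [GenotypeMatrix-class]
#' @param maxMissing maximum tolerated missing-call fraction (default 0.20)
#' @return the filtered GenotypeMatrix, with a `"missing-individuals"`
#'   [FilterReport-class] appended (see [filterReports()])
#' @export
filterIndividuals <- function(g, maxMissing = 0.20) {
  stopifnot(maxMissing >= 0, maxMissing <= 1)
  miss <- missingnessOf(g)
  keep <- miss <= maxMissing
  if (!any(keep)) stop("all individuals exceed the missingness threshold")
  out <- g[, keep]
  .appendReport(out, new("FilterReport",
                         rule = "missing-individuals", axis = "individual",
                         nRemoved = as.integer(sum(!keep)),
                         nRetained = as.integer(sum(keep)),
                         params = list(maxMissing = maxMissing)))
}

.lociStats <- function(g) {
  a <- SummarizedExperiment::assay(g, "calls")   # loci x individuals
  nCalled <- rowSums(!is.na(a))
  nAlt <- rowSums(a, na.rm = TRUE)
  altFreq <- ifelse(nCalled > 0, nAlt / (2 * nCalled), NA_real_)
  list(nCalled = nCalled, callRate = nCalled / ncol(a),
       altFreq = altFreq,
       maf = pmin(altFreq, 1 - altFreq),
       nHet = rowSums(a == 1, na.rm = TRUE),
       nHomRef = rowSums(a == 0, na.rm = TRUE),
       nHomAlt = rowSums(a == 2, na.rm = TRUE))
}

#' Locus-level filtering: HWE, call rate, minor allele frequency
#'
#' Applies, in order: (1) the exact Hardy-Weinberg test at `hweAlpha`
#' (loci with p below alpha removed); (2) call rate (fraction of
#' non-missing calls must be >= `minCallRate`); (3) minor allele frequency
#' computed from non-missing calls (must be >= `minMaf`). A locus with zero
#' calls is removed by the call-rate rule. One [FilterReport-class] is
#' appended per rule.
#'
#' @param g a [GenotypeMatrix-class]
#' @param hweAlpha HWE rejection level (default 0.05)
#' @param minCallRate minimum fraction of individuals called (default 0.75)
#' @param minMaf minimum minor allele frequency (default 0.05)
#' @export
filterLoci <- function(g, hweAlpha = 0.05, minCallRate = 0.75,
                       minMaf = 0.05) {
  stopifnot(ncol(g) > 0, nrow(g) > 0)
  st <- .lociStats(g)
  hweP <- mapply(hweExactTest, st$nHomRef, st$nHet, st$nHomAlt)
  keep <- is.na(hweP) | hweP >= hweAlpha
  keep[st$nCalled == 0] <- TRUE              # zero-call loci fall to call rate
  g <- .appendReport(g[keep, ], new("FilterReport",
    rule = "hwe", axis = "locus", nRemoved = as.integer(sum(!keep)),
    nRetained = as.integer(sum(keep)), params = list(alpha = hweAlpha)))

  st <- .lociStats(g)
  keep <- st$callRate >= minCallRate
  g <- .appendReport(g[keep, ], new("FilterReport",
    rule = "call-rate", axis = "locus", nRemoved = as.integer(sum(!keep)),
    nRetained = as.integer(sum(keep)),
    params = list(minCallRate = minCallRate)))

  st <- .lociStats(g)
  keep <- !is.na(st$maf) & st$maf >= minMaf
  .appendReport(g[keep, ], new("FilterReport",
    rule = "maf", axis = "locus", nRemoved = as.integer(sum(!keep)),
    nRetained = as.integer(sum(keep)), params = list(minMaf = minMaf)))
}

#' Thin loci by physical distance
#'
#' Greedy left-to-right scan within each scaffold: the first locus is kept
#' and any locus closer than `minSpacing` bp to the last kept locus is
#' dropped, so that retained loci on a scaffold are pairwise at least
#' `minSpacing` apart. The default spacing of 250 kbp corresponds, at 2.1 Mb
#' per centimorgan, to about eight SNPs per map unit (see
#' [snpsPerMapUnit()]), a density at which linkage between retained markers
#' is negligible.
#'
#' @param g a [GenotypeMatrix-class] (loci sorted by scaffold, position)
#' @param minSpacing minimum spacing in bp (default 250000)
#' @export
thinByDistance <- function(g, minSpacing = 250000L) {
  loci <- lociTable(g)
  keep <- logical(nrow(loci))
  lastPos <- -Inf; lastScaf <- ""
  for (i in seq_len(nrow(loci))) {
    if (loci$scaffold[i] != lastScaf ||
        loci$position[i] - lastPos >= minSpacing) {
      keep[i] <- TRUE
      lastScaf <- loci$scaffold[i]
      lastPos <- loci$position[i]
    }
  }
  .appendReport(g[keep, ], new("FilterReport",
    rule = "thin", axis = "locus", nRemoved = as.integer(sum(!keep)),
    nRetained = as.integer(sum(keep)),
    params = list(minSpacing = minSpacing)))
}

#' SNP density per map unit implied by a physical thinning distance
#'
#' With a genome-wide recombination density of `mbPerCm` megabases per
#' centimorgan, a thinning spacing of `spacingBp` yields
#' `mbPerCm * 1e6 / spacingBp` retained markers per map unit, reported
#' rounded to the nearest integer (2.1 Mb/cM and 250 kbp give 8).
#'
#' @param spacingBp thinning distance in bp
#' @param mbPerCm megabases per centimorgan
#' @export
snpsPerMapUnit <- function(spacingBp = 250000, mbPerCm = 2.1) {
  round(mbPerCm * 1e6 / spacingBp)
}

#' Write genotypes as a compact TSV table
#'
#' Individuals x loci dosage codes with `.` for missing; first column `id`,
#' second `site`.
#' @param g a [GenotypeMatrix-class]
#' @param path output path
#' @export
writeGenotypeTsv <- function(g, path) {
  d <- dosageMatrix(g)
  out <- cbind(id = rownames(d), site = unname(siteOf(g)),
               as.data.frame(ifelse(is.na(d), ".", d)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise the accumulated filter reports as JSON
#' @param g a [GenotypeMatrix-class]
#' @param path output path
#' @export
writeFilterReportJson <- function(g, path) {
  reps <- lapply(filterReports(g), function(r)
    list(rule = r@rule, axis = r@axis, nRemoved = r@nRemoved,
         nRetained = r@nRetained, params = r@params))
  jsonlite::write_json(reps, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
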