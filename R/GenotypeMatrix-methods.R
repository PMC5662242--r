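#' Construct a GenotypeMatrix
#'
#' @param calls numeric matrix of alternate-allele dosages, individuals in
#'   rows and loci in columns; `NA` marks a missing call.
#' @param loci data.frame with columns `scaffold`, `position` (bp, >= 0) and
#'   optionally `ref`, `alt`. One row per locus, in the column order of
#'   `calls`; loci are re-sorted by (scaffold, position) on construction.
#' @param samples data.frame with columns `id`, `site` and optionally `x`,
#'   `y` (projected metres). One row per individual, in the row order of
#'   `calls`.
#'
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = rbind(a = c(0, 1), b = c(2, NA), c = c(1, 1)),
#'   loci = data.frame(scaffold = "s1", position = c(100, 500e3),
#'                     ref = "A", alt = "T"),
#'   samples = data.frame(id = c("a", "b", "c"), site = c("S1", "S1", "S2"),
#'                        x = c(0, 10, 5000), y = c(0, 20, 100)))
#' dosageMatrix(gm)
#' @export
GenotypeMatrix <- function(calls, loci, samples) {
  calls <- as.matrix(calls)
  stopifnot(nrow(samples) == nrow(calls), nrow(loci) == ncol(calls))
  if (is.null(loci$ref)) loci$ref <- "A"
  if (is.null(loci$alt)) loci$alt <- "T"
  if (is.null(samples$x)) samples$x <- NA_real_
  if (is.null(samples$y)) samples$y <- NA_real_
  if (any(loci$position < 0)) stop("locus positions must be non-negative")
  o <- order(as.character(loci$scaffold), loci$position)
  loci <- loci[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(loci$scaffold),
    ranges = IRanges::IRanges(start = loci$position, width = 1L),
    ref = as.character(loci$ref), alt = as.character(loci$alt))
  names(rr) <- paste(loci$scaffold, loci$position, sep = ":")
  ids <- as.character(samples$id)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  assay <- t(calls)
  dimnames(assay) <- list(names(rr), ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = assay), rowRanges = rr,
    colData = S4Vectors::DataFrame(
      site = as.character(samples$site), x = samples$x, y = samples$y,
      row.names = ids))
  new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix-class
#' @param x a GenotypeMatrix
#' @export
setMethod("dosageMatrix", "GenotypeMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "calls"))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) colnames(x))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("siteOf", "GenotypeMatrix", function(x) {
  setNames(SummarizedExperiment::colData(x)$site, colnames(x))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("coordsOf", "GenotypeMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(x = cd$x, y = cd$y)
  rownames(m) <- colnames(x)
  m
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lociTable", "GenotypeMatrix", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(scaffold = as.character(GenomicRanges::seqnames(rr)),
             position = GenomicRanges::start(rr),
             ref = rr$ref, alt = rr$alt, row.names = names(rr))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("missingnessOf", "GenotypeMatrix", function(x) {
  a <- SummarizedExperiment::assay(x, "calls")
  colMeans(is.na(a))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("filterReports", "GenotypeMatrix", function(x) {
  reps <- S4Vectors::metadata(x)$filterReports
  if (is.null(reps)) list() else reps
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", ncol(object), "individuals x", nrow(object),
      "loci\n")
  cat("  sites:", paste(unique(SummarizedExperiment::colData(object)$site),
                        collapse = " "), "\n")
  cat("  missing calls:",
      sprintf("%.2f%%",
              100 * mean(is.na(SummarizedExperiment::assay(object, "calls")))),
      "\n")
  reps <- filterReports(object)
  if (length(reps))
    cat("  filters applied:",
        paste(vapply(reps, function(r) r@rule, ""), collapse = " -> "), "\n")
})

.appendReport <- function(gm, report) {
  md <- S4Vectors::metadata(gm)
  md$filterReports <- c(md$filterReports, list(report))
  S4Vectors::metadata(gm) <- md
  gm
}

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport [%s/%s]: removed %d, retained %d\n",
              object@rule, object@axis, object@nRemoved, object@nRetained))
  if (length(object@params))
    cat("  params:", paste(names(object@params), unlist(object@params),
                           sep = "=", collapse = ", "), "\n")
})
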