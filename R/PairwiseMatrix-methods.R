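#' Construct a PairwiseMatrix
#'
#' @param values square symmetric numeric matrix; dimnames are used as
#'   labels (generated if absent).
#' @param kind tag describing the values (`"genetic-distance"`, `"kinship"`,
#'   `"geographic"`, `"isolation"`, `"barrier"` or `"generic"`).
#' @param labels optional character vector overriding the dimnames.
#' @return a [PairwiseMatrix-class]
#' @export
PairwiseMatrix <- function(values, kind = "generic", labels = NULL) {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (is.null(rownames(values))) {
    lab <- paste0("i", seq_len(nrow(values)))
    dimnames(values) <- list(lab, lab)
  }
  new("PairwiseMatrix", values = values, kind = kind)
}

#' @rdname PairwiseMatrix-class
#' @param x a PairwiseMatrix
#' @export
setMethod("pairKind", "PairwiseMatrix", function(x) x@kind)

#' @rdname PairwiseMatrix-class
#' @export
setMethod("pairLabels", "PairwiseMatrix", function(x) rownames(x@values))

#' @rdname PairwiseMatrix-class
#' @details `upperTriangle()` returns the strictly-upper-triangle entries
#'   column-wise, the vectorization over which Mantel statistics are defined.
#' @export
setMethod("upperTriangle", "PairwiseMatrix", function(x) {
  x@values[upper.tri(x@values)]
})

#' @export
setMethod("dim", "PairwiseMatrix", function(x) dim(x@values))

#' @rdname PairwiseMatrix-class
#' @param ... unused
#' @method as.matrix PairwiseMatrix
#' @export
as.matrix.PairwiseMatrix <- function(x, ...) x@values

setMethod("as.matrix", "PairwiseMatrix", as.matrix.PairwiseMatrix)

setMethod("show", "PairwiseMatrix", function(object) {
  v <- upperTriangle(object)
  cat(sprintf("PairwiseMatrix [%s]: %d labels; range %.4g .. %.4g (%d NA)\n",
              object@kind, nrow(object@values),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

# align a list of PairwiseMatrix to a common label order; errors on mismatch
.alignPairwise <- function(..., labels = NULL) {
  ms <- list(...)
  if (is.null(labels)) labels <- pairLabels(ms[[1]])
  lapply(ms, function(m) {
    if (!all(labels %in% pairLabels(m)))
      stop("pairwise matrices carry different label sets")
    m@values[labels, labels]
  })
}

#' Write a PairwiseMatrix as square labelled CSV
#' @param x a PairwiseMatrix
#' @param path output file
#' @export
writePairwiseCsv <- function(x, path) {
  write.csv(as.matrix(x), path, quote = FALSE)
  invisible(path)
}

#' Read a square labelled CSV as a PairwiseMatrix
#' @param path input file
#' @param kind kind tag to attach
#' @export
readPairwiseCsv <- function(path, kind = "generic") {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  PairwiseMatrix(m, kind = kind)
}
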