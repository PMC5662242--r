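#' @rdname GenotypeMatrix-class
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("coordsOf", function(x) standardGeneric("coordsOf"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("missingnessOf", function(x) standardGeneric("missingnessOf"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("filterReports", function(x) standardGeneric("filterReports"))

#' @rdname PairwiseMatrix-class
#' @export
setGeneric("pairKind", function(x) standardGeneric("pairKind"))

#' @rdname PairwiseMatrix-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname PairwiseMatrix-class
#' @export
setGeneric("upperTriangle", function(x) standardGeneric("upperTriangle"))

#' @rdname OrdinationModel-class
#' @export
setGeneric("termTable", function(x) standardGeneric("termTable"))

#' @rdname OrdinationModel-class
#' @export
setGeneric("adjustedR2", function(x) standardGeneric("adjustedR2"))
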