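#' @rdname VariantMatrix
#' @param x,object A VariantMatrix.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname VariantMatrix
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname VariantMatrix
#' @param chrom Chromosome identifier.
#' @export
setGeneric("positions", function(x, chrom) standardGeneric("positions"))

#' @rdname VariantMatrix
#' @export
setGeneric("genotypes", function(x, chrom) standardGeneric("genotypes"))

#' @rdname VariantMatrix
#' @export
setGeneric("nSites", function(x, chrom) standardGeneric("nSites"))

#' @rdname neutralityIndex
#' @export
setGeneric("neutralityIndex", function(x, ...) standardGeneric("neutralityIndex"))

#' @rdname MKTable
#' @param x An MKTable.
#' @export
setGeneric("mkCounts", function(x) standardGeneric("mkCounts"))

#' @rdname MKTable
#' @export
setGeneric("mkRatios", function(x) standardGeneric("mkRatios"))
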