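#' @rdname VariantMatrix
#' @export
setMethod("sampleNames", "VariantMatrix", function(x) x@samples)

#' @rdname VariantMatrix
#' @export
setMethod("chromNames", "VariantMatrix", function(x) names(x@pos))

#' @rdname VariantMatrix
#' @export
setMethod("positions", "VariantMatrix", function(x, chrom) {
  .checkChrom(x, chrom)
  x@pos[[chrom]]
})

#' @rdname VariantMatrix
#' @export
setMethod("genotypes", "VariantMatrix", function(x, chrom) {
  .checkChrom(x, chrom)
  x@geno[[chrom]]
})

#' @rdname VariantMatrix
#' @export
setMethod("nSites", "VariantMatrix", function(x, chrom) {
  .checkChrom(x, chrom)
  length(x@pos[[chrom]])
})

.checkChrom <- function(x, chrom) {
  if (!chrom %in% names(x@pos))
    stop("chromosome not present in VariantMatrix: ", chrom, call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "VariantMatrix", function(object) {
  cat("VariantMatrix with", length(object@samples), "samples,",
      length(object@pos), "chromosome(s)\n")
  for (chrom in names(object@pos))
    cat("  ", chrom, ": ", length(object@pos[[chrom]]), " sites\n", sep = "")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment", object@geneID, "-",
      length(object@ingroup), "ingroup /",
      length(object@outgroup), "outgroup sequences,",
      if (length(object@ingroup)) Biostrings::width(object@ingroup)[1] else 0, "bp",
      if (object@valid) "" else paste0("[INVALID: ", object@invalidReason, "]"),
      "\n")
})

#' @rdname MKTable
#' @export
setMethod("mkCounts", "MKTable", function(x)
  c(PN = x@PN, PS = x@PS, DN = x@DN, DS = x@DS))

#' MK-table derived ratios
#'
#' `mkRatios` returns PN/PS and DN/DS (NA where the denominator is zero);
#' `neutralityIndex` returns NI = (PN/PS)/(DN/DS), defined when PS > 0 and
#' DN > 0 (and DS > 0); otherwise NA with a `reason` attribute.
#'
#' @rdname MKTable
#' @export
setMethod("mkRatios", "MKTable", function(x) {
  c(PN_PS = if (x@PS > 0) x@PN / x@PS else NA_real_,
    DN_DS = if (x@DS > 0) x@DN / x@DS else NA_real_)
})

#' Neutrality index
#'
#' NI = (PN/PS)/(DN/DS).  Values above 1 are consistent with segregating
#' slightly deleterious nonsynonymous variants (relaxed/negative selection);
#' values below 1 with an excess of nonsynonymous fixations (positive
#' selection).
#'
#' @param x An [MKTable-class].
#' @param ... Unused.
#' @return Numeric NI, or NA with attribute `reason` when undefined
#'   (PS = 0, DS = 0 or DN = 0).
#' @examples
#' neutralityIndex(MKTable(PN = 1, PS = 1, DN = 1, DS = 1))
#' @export
setMethod("neutralityIndex", "MKTable", function(x, ...) {
  if (x@PS <= 0) return(structure(NA_real_, reason = "PS == 0"))
  if (x@DS <= 0) return(structure(NA_real_, reason = "DS == 0"))
  if (x@DN <= 0) return(structure(NA_real_, reason = "DN == 0"))
  (x@PN / x@PS) / (x@DN / x@DS)
})

setMethod("show", "MKTable", function(object) {
  r <- mkRatios(object)
  ni <- neutralityIndex(object)
  cat("MKTable", if (!is.na(object@label)) paste0("[", object@label, "]") else "",
      sprintf("PN=%g PS=%g DN=%g DS=%g | PN/PS=%.3g DN/DS=%.3g NI=%.3g\n",
              object@PN, object@PS, object@DN, object@DS,
              r[["PN_PS"]], r[["DN_DS"]], as.numeric(ni)))
})
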