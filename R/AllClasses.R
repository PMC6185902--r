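#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats quantile rpois runif rbinom setNames pt sd var
#' @importFrom utils read.table write.table head tail
NULL

## Integer allele codes used throughout: A=0, C=1, G=2, T=3, missing=-1.
MISSING_CODE <- -1L
BASES <- c("A", "C", "G", "T")

#' Haploid variant matrix
#'
#' Ordered haploid samples by ascending variant positions, one block per
#' chromosome.  Alleles are integer coded (A=0, C=1, G=2, T=3) with -1 marking
#' a missing call.  Objects are normally created by [readVariants()] or by the
#' synthetic-data generator, not by hand.
#'
#' @slot samples Ordered character vector of sample identifiers.
#' @slot pos Named list (one element per chromosome) of strictly increasing
#'   integer position vectors (1-based).
#' @slot geno Named list of integer matrices, samples x sites, rows in the
#'   order of `samples`.
#'
#' @aliases VariantMatrix-class
#' @exportClass VariantMatrix
setClass("VariantMatrix",
  representation(samples = "character", pos = "list", geno = "list"))

setValidity("VariantMatrix", function(object) {
  msg <- character()
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample identifiers must be unique")
  if (!identical(names(object@pos), names(object@geno)))
    msg <- c(msg, "pos and geno must name the same chromosomes")
  for (chrom in names(object@pos)) {
    p <- object@pos[[chrom]]
    g <- object@geno[[chrom]]
    if (!is.matrix(g) || nrow(g) != length(object@samples))
      msg <- c(msg, sprintf("geno[[%s]]: one row per sample required", chrom))
    else if (ncol(g) != length(p))
      msg <- c(msg, sprintf("geno[[%s]]: one column per position required", chrom))
    if (length(p) > 1L && any(diff(p) <= 0L))
      msg <- c(msg, sprintf("positions on %s must be strictly increasing", chrom))
    if (length(g) && !all(g %in% c(-1L, 0L, 1L, 2L, 3L)))
      msg <- c(msg, sprintf("allele codes on %s outside {-1,0,1,2,3}", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantMatrix
#'
#' @param samples Character vector of sample ids.
#' @param pos Named list of integer position vectors per chromosome.
#' @param geno Named list of samples x sites integer matrices.
#' @return A [VariantMatrix-class] object.
#' @export
VariantMatrix <- function(samples, pos, geno) {
  pos <- lapply(pos, as.integer)
  geno <- lapply(geno, function(g) {
    storage.mode(g) <- "integer"
    rownames(g) <- samples
    g
  })
  new("VariantMatrix", samples = as.character(samples), pos = pos, geno = geno)
}

#' Codon alignment of one gene
#'
#' Spliced CDS haplotypes of one gene: ingroup sequences plus optional
#' outgroup sequences, all of equal length and a multiple of three.  Genes
#' with internal stop codons or off-frame lengths are flagged invalid and
#' skipped by downstream statistics.
#'
#' @slot geneID Gene identifier.
#' @slot ingroup [Biostrings::DNAStringSet] of ingroup CDS haplotypes.
#' @slot outgroup [Biostrings::DNAStringSet] of outgroup CDS haplotypes
#'   (may be empty).
#' @slot valid Logical; FALSE when the gene fails frame/stop validation.
#' @slot invalidReason Character; why the gene was flagged.
#'
#' @aliases CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(geneID = "character", ingroup = "DNAStringSet",
                 outgroup = "DNAStringSet", valid = "logical",
                 invalidReason = "character"))

setValidity("CodonAlignment", function(object) {
  lens <- c(Biostrings::width(object@ingroup), Biostrings::width(object@outgroup))
  if (length(unique(lens)) > 1L)
    return("all sequences must have equal length")
  TRUE
})

#' Construct a CodonAlignment
#'
#' Validates frame (length divisible by 3) and internal stop codons; failures
#' mark the gene invalid rather than erroring, so whole-genome sweeps can
#' skip and log them.
#'
#' @param geneID Gene identifier.
#' @param ingroup,outgroup DNAStringSet (or named character vector) of spliced
#'   CDS haplotypes.
#' @return A [CodonAlignment-class] object.
#' @export
CodonAlignment <- function(geneID, ingroup, outgroup = Biostrings::DNAStringSet()) {
  if (!methods::is(ingroup, "DNAStringSet"))
    ingroup <- Biostrings::DNAStringSet(ingroup)
  if (!methods::is(outgroup, "DNAStringSet"))
    outgroup <- Biostrings::DNAStringSet(outgroup)
  valid <- TRUE; reason <- NA_character_
  len <- unique(c(Biostrings::width(ingroup), Biostrings::width(outgroup)))
  if (length(len) != 1L) {
    valid <- FALSE; reason <- "unequal sequence lengths"
    len <- len[1L]
  } else if (len %% 3L != 0L) {
    valid <- FALSE; reason <- "length not a multiple of 3"
  } else if (.hasInternalStop(c(as.character(ingroup), as.character(outgroup)))) {
    valid <- FALSE; reason <- "internal stop codon"
  }
  new("CodonAlignment", geneID = as.character(geneID), ingroup = ingroup,
      outgroup = outgroup, valid = valid, invalidReason = reason)
}

.hasInternalStop <- function(seqs) {
  stops <- c("TAA", "TAG", "TGA")
  for (s in seqs) {
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 3L, by = 3L)  # exclude terminal codon
    cods <- substring(s, starts, starts + 2L)
    if (any(cods %in% stops)) return(TRUE)
  }
  FALSE
}

#' McDonald-Kreitman count table
#'
#' Pooled polymorphism (PN, PS) and fixed-divergence (DN, DS) counts at
#' nonsynonymous and synonymous sites, with the derived ratios and the
#' neutrality index NI = (PN/PS)/(DN/DS).
#'
#' @slot PN,PS,DN,DS Non-negative counts (may be fractional after
#'   pathway-averaged classification or length rescaling).
#' @slot label Partition label (gene, chromosome or region name).
#'
#' @aliases MKTable-class
#' @exportClass MKTable
setClass("MKTable",
  representation(PN = "numeric", PS = "numeric", DN = "numeric",
                 DS = "numeric", label = "character"))

setValidity("MKTable", function(object) {
  counts <- c(object@PN, object@PS, object@DN, object@DS)
  if (any(!is.finite(counts)) || any(counts < 0))
    return("counts must be finite and non-negative")
  TRUE
})

#' Construct an MKTable
#'
#' @param PN,PS Nonsynonymous / synonymous polymorphism counts.
#' @param DN,DS Nonsynonymous / synonymous fixed-divergence counts.
#' @param label Optional partition label.
#' @return An [MKTable-class] object.
#' @export
MKTable <- function(PN, PS, DN, DS, label = NA_character_) {
  new("MKTable", PN = as.numeric(PN), PS = as.numeric(PS),
      DN = as.numeric(DN), DS = as.numeric(DS), label = as.character(label))
}
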