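#' Reconstruct spliced CDS haplotypes from a reference and a variant matrix
#'
#' For each gene and sample, substitutes the sample's alleles into the
#' reference CDS, splices the exons in genomic order and reverse-complements
#' minus-strand genes.  Missing calls become N (the affected codon is then
#' skipped by the codon statistics).
#'
#' @param genome Reference `DNAStringSet`.
#' @param vm A [VariantMatrix-class] (unfiltered or filtered; sites outside
#'   CDS are ignored).
#' @param models Gene-model list from [readGeneModels()].
#' @param ingroup,outgroup Sample id vectors.
#' @return A named list of [CodonAlignment-class] objects (invalid genes
#'   included, flagged).
#' @export
buildCodonAlignments <- function(genome, vm, models, ingroup,
                                 outgroup = character(0)) {
  stopifnot(all(c(ingroup, outgroup) %in% sampleNames(vm)))
  samples <- c(ingroup, outgroup)
  out <- list()
  for (m in models) {
    chrom <- m$chrom
    if (!chrom %in% names(genome)) next
    has_vars <- chrom %in% chromNames(vm)
    p <- if (has_vars) positions(vm, chrom) else integer(0)
    g <- if (has_vars) genotypes(vm, chrom) else NULL
    spliced <- setNames(character(length(samples)), samples)
    ref_parts <- character(length(m$cds))
    var_parts <- vector("list", length(m$cds))
    for (e in seq_along(m$cds)) {
      s <- GenomicRanges::start(m$cds)[e]; en <- GenomicRanges::end(m$cds)[e]
      ref_parts[e] <- as.character(Biostrings::subseq(genome[[chrom]], s, en))
      var_parts[[e]] <- which(p >= s & p <= en)
    }
    for (smp in samples) {
      parts <- ref_parts
      for (e in seq_along(m$cds)) {
        idx <- var_parts[[e]]
        if (!length(idx)) next
        s <- GenomicRanges::start(m$cds)[e]
        chars <- strsplit(parts[e], "")[[1]]
        codes <- g[smp, idx]
        off <- p[idx] - s + 1L
        chars[off] <- ifelse(codes == MISSING_CODE, "N", BASES[codes + 1L])
        parts[e] <- paste(chars, collapse = "")
      }
      seq <- paste(parts, collapse = "")
      if (m$strand == "-")
        seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      spliced[smp] <- seq
    }
    aln <- CodonAlignment(m$geneID,
                          ingroup = spliced[ingroup],
                          outgroup = spliced[outgroup])
    if (!m$valid) {
      aln@valid <- FALSE
      aln@invalidReason <- "gene model flagged invalid"
    }
    out[[m$geneID]] <- aln
  }
  out
}

#' Collapse identical ingroup haplotypes
#'
#' Optional haplotype de-duplication before diversity calculation: identical
#' ingroup CDS sequences are collapsed to one representative each.
#'
#' @param aln A [CodonAlignment-class].
#' @return A [CodonAlignment-class] with duplicated ingroup sequences removed.
#' @export
dedupHaplotypes <- function(aln) {
  seqs <- as.character(aln@ingroup)
  keep <- !duplicated(seqs)
  out <- aln
  out@ingroup <- aln@ingroup[keep]
  out
}
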