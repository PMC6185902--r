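#' Remove repeat-region and missing-data sites
#'
#' Drops every site falling inside a repeat annotation and every site with a
#' missing call in any sample, mirroring the standard SNP-matrix cleaning
#' applied before window-based phylogenetic analysis.  Idempotent; sample
#' order is preserved.
#'
#' @param vm A [VariantMatrix-class].
#' @param repeats A `GRanges` of repeat annotations (e.g. from
#'   [readRepeatMasker()]); `NULL` skips the repeat filter.
#' @return A filtered [VariantMatrix-class].
#' @export
filterVariants <- function(vm, repeats = NULL) {
  pos_l <- list(); geno_l <- list()
  n_rep <- 0L; n_miss <- 0L
  for (chrom in chromNames(vm)) {
    p <- positions(vm, chrom); g <- genotypes(vm, chrom)
    keep <- rep(TRUE, length(p))
    if (!is.null(repeats) && length(repeats)) {
      sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p, p))
      hit <- IRanges::overlapsAny(sites, repeats)
      n_rep <- n_rep + sum(hit & keep)
      keep <- keep & !hit
    }
    miss <- colSums(g == MISSING_CODE) > 0L
    n_miss <- n_miss + sum(miss & keep)
    keep <- keep & !miss
    pos_l[[chrom]] <- p[keep]
    geno_l[[chrom]] <- g[, keep, drop = FALSE]
  }
  if (n_rep + n_miss > 0)
    .log("filterVariants: removed ", n_rep, " repeat-region and ",
         n_miss, " missing-data site(s)")
  out <- VariantMatrix(sampleNames(vm), pos_l, geno_l)
  if (all(vapply(pos_l, length, 1L) == 0L))
    .log("filterVariants: no sites retained")
  out
}

#' Non-overlapping windows of a fixed number of variable sites
#'
#' Splits the variable sites of one chromosome into consecutive blocks of
#' exactly `nSitesPerWindow` sites (the sliding-window unit of the monophyly
#' scan).  A trailing partial block is dropped, with the count reported.
#'
#' @param vm A filtered [VariantMatrix-class].
#' @param chrom Chromosome identifier.
#' @param nSitesPerWindow Number of variable sites per window (default 50).
#' @return A `GRanges`, one range per window spanning the first to last site
#'   position of the block, with mcols `siteStart`, `siteEnd` (1-based site
#'   indices into the chromosome's position vector).
#' @export
variableSiteWindows <- function(vm, chrom, nSitesPerWindow = 50L) {
  .checkChrom(vm, chrom)
  stopifnot(nSitesPerWindow >= 1L)
  p <- positions(vm, chrom)
  S <- length(p)
  n_win <- S %/% nSitesPerWindow
  dropped <- S - n_win * nSitesPerWindow
  if (dropped > 0)
    .log("variableSiteWindows: trailing partial window of ", dropped,
         " site(s) dropped on ", chrom)
  if (n_win == 0L)
    return(GenomicRanges::GRanges(siteStart = integer(), siteEnd = integer()))
  siteStart <- (seq_len(n_win) - 1L) * nSitesPerWindow + 1L
  siteEnd <- siteStart + nSitesPerWindow - 1L
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(p[siteStart], p[siteEnd]),
                         siteStart = siteStart, siteEnd = siteEnd)
}

#' Fixed-width sliding windows over a chromosome
#'
#' Windows start at 0, `step`, 2*`step`, ... (0-based genomic offsets) and a
#' window is emitted only when it fits entirely on the chromosome.  With
#' `step == size` this tiles the chromosome prefix without overlap.
#'
#' @param chromLength Chromosome length in bp.
#' @param size Window size in bp.
#' @param step Step size in bp.
#' @param chrom Chromosome name for the returned ranges.
#' @return A `GRanges` of windows (1-based, inclusive coordinates).
#' @export
fixedWindows <- function(chromLength, size, step = size, chrom = "chr") {
  stopifnot(size >= 1L, step >= 1L)
  if (chromLength < size)
    return(GenomicRanges::GRanges())
  starts0 <- seq.int(0L, by = step,
                     length.out = (chromLength - size) %/% step + 1L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts0 + 1L, starts0 + size))
}
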