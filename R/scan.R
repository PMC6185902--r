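#' Sliding-window monophyly scan of one chromosome
#'
#' The recombination scanner: splits the chromosome's variable sites into
#' non-overlapping windows of `nSitesPerWindow` sites, builds a BioNJ tree
#' per window from p-distances, roots it on the outgroup, classifies which
#' focal samples form a monophyletic group (optionally jointly with an
#' anchor sample), attaches bootstrap support, and summarizes category
#' proportions in bins of consecutive windows.
#'
#' @param vm A filtered [VariantMatrix-class].
#' @param chrom Chromosome to scan.
#' @param focal Character vector of focal sample ids (e.g. the killer
#'   strains).
#' @param outgroup Character vector of outgroup sample ids used for rooting.
#' @param nSitesPerWindow Variable sites per window (default 50).
#' @param reps Bootstrap replicates per window; 0 skips support computation.
#' @param bin Number of consecutive windows per summary bin (default 50).
#' @param anchor Optional anchor sample id for joint-monophyly scans.
#' @param seed Integer seed; one resampling stream is derived per window.
#' @return A list with `calls` (a `GRanges`, one range per window, mcols
#'   `category` — comma-joined sorted ids, `""` for no grouping —, `support`
#'   and `anchorPresent`) and `bins` (a data.frame of per-bin category
#'   proportions; proportions sum to 1 within each bin, the final partial
#'   bin is reported with its actual size).
#' @export
scanChromosome <- function(vm, chrom, focal, outgroup, nSitesPerWindow = 50L,
                           reps = 100L, bin = 50L, anchor = NULL, seed = 1L) {
  stopifnot(all(focal %in% sampleNames(vm)), all(outgroup %in% sampleNames(vm)))
  if (!is.null(anchor)) stopifnot(anchor %in% sampleNames(vm))
  wins <- variableSiteWindows(vm, chrom, nSitesPerWindow)
  g <- genotypes(vm, chrom)
  n_win <- length(wins)
  category <- character(n_win)
  support <- rep(NA_real_, n_win)

  old <- options(meiodrive.verbose = FALSE)  # silence per-window clamp notes
  on.exit(options(old))
  for (w in seq_len(n_win)) {
    cols <- wins$siteStart[w]:wins$siteEnd[w]
    gw <- g[, cols, drop = FALSE]
    if (reps > 0L) {
      bs <- bootstrapSupport(gw, focal, outgroup, reps = reps,
                             seed = .childSeed(seed, w), anchor = anchor)
      cat_w <- bs$category; support[w] <- bs$support
    } else {
      cat_w <- tryCatch(.windowCategory(gw, focal, outgroup, anchor),
                        error = function(e) character(0))
    }
    category[w] <- paste(cat_w, collapse = ",")
  }
  options(old); on.exit()

  wins$category <- category
  wins$support <- support
  wins$anchorPresent <- !is.null(anchor) & nzchar(category)
  list(calls = wins, bins = .binSummary(category, bin))
}

## per-bin proportions of each observed category over blocks of `bin` windows
.binSummary <- function(category, bin) {
  n <- length(category)
  if (n == 0L)
    return(data.frame(bin = integer(), windowStart = integer(),
                      windowEnd = integer(), size = integer(),
                      category = character(), proportion = numeric()))
  bin_id <- (seq_len(n) - 1L) %/% bin + 1L
  out <- do.call(rbind, lapply(split(seq_len(n), bin_id), function(idx) {
    tab <- table(category[idx])
    data.frame(bin = bin_id[idx[1]], windowStart = idx[1],
               windowEnd = idx[length(idx)], size = length(idx),
               category = names(tab),
               proportion = as.numeric(tab) / length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise divergence between two samples in sliding windows
#'
#' Per fixed-width window, the number of variable sites at which the two
#' samples differ, divided by the window length in bp.
#'
#' @param vm A [VariantMatrix-class].
#' @param chrom Chromosome.
#' @param sampleA,sampleB Sample ids.
#' @param windowSize,step Window size and step in bp (defaults 10 kb / 2 kb).
#' @param chromLength Chromosome length in bp; defaults to the last variant
#'   position.
#' @return A `GRanges` of windows with mcols `nDiff` and `divergence`
#'   (differences per bp).
#' @export
pairwiseDivergenceScan <- function(vm, chrom, sampleA, sampleB,
                                   windowSize = 10000L, step = 2000L,
                                   chromLength = NULL) {
  stopifnot(all(c(sampleA, sampleB) %in% sampleNames(vm)))
  p <- positions(vm, chrom)
  g <- genotypes(vm, chrom)
  if (is.null(chromLength)) chromLength <- if (length(p)) max(p) else windowSize
  wins <- fixedWindows(chromLength, windowSize, step, chrom = chrom)
  a <- g[sampleA, ]; b <- g[sampleB, ]
  diff_pos <- p[a != b & a != MISSING_CODE & b != MISSING_CODE]
  if (length(diff_pos)) {
    sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(diff_pos, diff_pos))
    nDiff <- GenomicRanges::countOverlaps(wins, sites)
  } else {
    nDiff <- integer(length(wins))
  }
  wins$nDiff <- nDiff
  wins$divergence <- nDiff / windowSize
  wins
}
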