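## Nei-Gojobori (1986) style codon machinery.  Site counts and
## pathway-averaged difference counts are precomputed once per session for
## all sense codons and cached.

.ngEnv <- new.env(parent = emptyenv())

.geneticCode <- function() Biostrings::GENETIC_CODE

.ngTables <- function() {
  if (!is.null(.ngEnv$siteN)) return(invisible(NULL))
  gc_map <- .geneticCode()
  codons <- names(gc_map)
  sense <- codons[gc_map != "*"]
  siteS <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s_total <- 0
    for (p in 1:3) {
      base <- substr(cod, p, p)
      muts <- vapply(setdiff(BASES, base), function(b) {
        m <- cod; substr(m, p, p) <- b; m
      }, "")
      aam <- gc_map[muts]
      n_stop <- sum(aam == "*")
      n_syn <- sum(aam == gc_map[[cod]] & aam != "*")
      denom <- 3 - n_stop
      if (denom > 0) s_total <- s_total + n_syn / denom
    }
    siteS[cod] <- s_total
  }
  .ngEnv$sense <- sense
  .ngEnv$siteS <- siteS
  .ngEnv$siteN <- 3 - siteS
  .ngEnv$pairN <- matrix(NA_real_, length(sense), length(sense),
                         dimnames = list(sense, sense))
  .ngEnv$pairS <- .ngEnv$pairN
  invisible(NULL)
}

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' Over the nine single-nucleotide mutants of the codon, the synonymous site
#' count is the per-position fraction of synonymous changes summed over the
#' three positions, with mutations to stop codons excluded from each
#' position's denominator; the nonsynonymous count is the complement to 3.
#'
#' @param codon A 3-letter string over A/C/G/T, not a stop codon.
#' @return Named numeric vector `c(N = ..., S = ...)`.
#' @examples
#' ng86SiteCounts("TTT")  # N = 8/3, S = 1/3
#' @export
ng86SiteCounts <- function(codon) {
  .ngTables()
  codon <- toupper(codon)
  if (!codon %in% .ngEnv$sense)
    stop("not a sense codon: ", codon, call. = FALSE)
  c(N = unname(.ngEnv$siteN[codon]), S = unname(.ngEnv$siteS[codon]))
}

#' Pathway-averaged codon difference counts
#'
#' Counts nonsynonymous and synonymous changes between two codons, averaged
#' over all minimal mutational pathways (1, 2 or 6 orderings of the
#' differing positions); pathways passing through a stop codon are excluded.
#' If every pathway is blocked by a stop, all pathways are used with
#' stop-involving steps counted as nonsynonymous.  The two counts always sum
#' to the Hamming distance.
#'
#' @param codonA,codonB Sense codons (3-letter A/C/G/T strings).
#' @return Named numeric vector `c(n = ..., s = ...)`.
#' @examples
#' pairwiseCodonDiffs("TTT", "GTA")  # c(n = 1.5, s = 0.5)
#' @export
pairwiseCodonDiffs <- function(codonA, codonB) {
  .ngTables()
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  if (!codonA %in% .ngEnv$sense || !codonB %in% .ngEnv$sense)
    stop("both codons must be sense codons", call. = FALSE)
  cached <- .ngEnv$pairN[codonA, codonB]
  if (!is.na(cached))
    return(c(n = cached, s = .ngEnv$pairS[codonA, codonB]))
  res <- .pathAverage(codonA, codonB)
  .ngEnv$pairN[codonA, codonB] <- res[["n"]]
  .ngEnv$pairN[codonB, codonA] <- res[["n"]]
  .ngEnv$pairS[codonA, codonB] <- res[["s"]]
  .ngEnv$pairS[codonB, codonA] <- res[["s"]]
  res
}

.pathAverage <- function(a, b) {
  gc_map <- .geneticCode()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  h <- length(pos)
  if (h == 0L) return(c(n = 0, s = 0))
  perms <- .permutations(pos)
  walk <- function(order, allow_stop) {
    cur <- a; n <- 0; s <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      aa1 <- gc_map[[cur]]; aa2 <- gc_map[[nxt]]
      if (aa2 == "*" && nxt != b && !allow_stop) return(NULL)
      if (aa1 == aa2 && aa1 != "*") s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(n = n, s = s)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(paths))
    paths <- lapply(perms, walk, allow_stop = TRUE)
  counts <- do.call(rbind, paths)
  c(n = mean(counts[, "n"]), s = mean(counts[, "s"]))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

.splitCodons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

.isSense <- function(codons) {
  .ngTables()
  codons %in% .ngEnv$sense
}

#' Within-group nucleotide diversity of one gene (piN, piS, pi_total)
#'
#' For every ingroup pair, nonsynonymous and synonymous differences are
#' summed over codons (pathway-averaged) and divided by the pair's NG86 site
#' counts (averaged over the two sequences); piN and piS are the means of
#' these per-pair ratios, and pi_total is the mean per-site pairwise
#' difference.  Codons with a stop or an ambiguous base in either member of
#' a pair are excluded for that pair.
#'
#' @param aln A [CodonAlignment-class] with >= 2 ingroup sequences.
#' @return A list: `piTotal`, `piN`, `piS`, `piNpiS`, `nSites`, `sSites`
#'   (pair-averaged fractional site counts), `meanNDiff`, `meanSDiff`
#'   (pair-averaged difference counts, for length-weighted pooling),
#'   `nPairs`.
#' @export
geneDiversity <- function(aln) {
  if (!aln@valid) stop("invalid gene: ", aln@invalidReason, call. = FALSE)
  seqs <- as.character(aln@ingroup)
  if (length(seqs) < 2L) stop("need >= 2 ingroup sequences", call. = FALSE)
  cods <- lapply(seqs, .splitCodons)
  idx <- utils::combn(length(seqs), 2)
  nd <- sd_ <- nsites <- ssites <- ntdiff <- ntlen <- numeric(ncol(idx))
  for (p in seq_len(ncol(idx))) {
    ca <- cods[[idx[1, p]]]; cb <- cods[[idx[2, p]]]
    ok <- .isSense(ca) & .isSense(cb)
    ca <- ca[ok]; cb <- cb[ok]
    Na <- sum(.ngEnv$siteN[ca]); Sa <- sum(.ngEnv$siteS[ca])
    Nb <- sum(.ngEnv$siteN[cb]); Sb <- sum(.ngEnv$siteS[cb])
    nsites[p] <- (Na + Nb) / 2; ssites[p] <- (Sa + Sb) / 2
    diff <- which(ca != cb)
    for (d in diff) {
      cnt <- pairwiseCodonDiffs(ca[d], cb[d])
      nd[p] <- nd[p] + cnt[["n"]]; sd_[p] <- sd_[p] + cnt[["s"]]
    }
    ntdiff[p] <- if (length(diff)) sum(mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
      ca[diff], cb[diff])) else 0
    ntlen[p] <- 3 * length(ca)
  }
  piN <- mean(nd / nsites); piS <- mean(sd_ / ssites)
  list(piTotal = mean(ntdiff / ntlen), piN = piN, piS = piS,
       piNpiS = if (piS > 0) piN / piS else NA_real_,
       nSites = mean(nsites), sSites = mean(ssites),
       meanNDiff = mean(nd), meanSDiff = mean(sd_),
       nPairs = ncol(idx))
}

#' Polymorphism counts of one gene (PN, PS)
#'
#' Counts segregating nonsynonymous and synonymous changes among the ingroup
#' sequences: per codon column with more than one distinct sense codon, the
#' pathway-averaged difference counts are averaged over the distinct codon
#' pairs (exact for a two-haplotype ingroup).
#'
#' @param aln A [CodonAlignment-class].
#' @return Named numeric `c(PN = ..., PS = ...)`.
#' @export
genePolymorphism <- function(aln) {
  if (!aln@valid) stop("invalid gene: ", aln@invalidReason, call. = FALSE)
  cods <- lapply(as.character(aln@ingroup), .splitCodons)
  n_cod <- length(cods[[1]])
  PN <- PS <- 0
  for (j in seq_len(n_cod)) {
    col <- vapply(cods, `[[`, "", j)
    if (!all(.isSense(col))) next
    u <- unique(col)
    if (length(u) < 2L) next
    pairs <- utils::combn(u, 2)
    cnt <- rowMeans(vapply(seq_len(ncol(pairs)), function(p)
      pairwiseCodonDiffs(pairs[1, p], pairs[2, p]), numeric(2)))
    PN <- PN + cnt[["n"]]; PS <- PS + cnt[["s"]]
  }
  c(PN = PN, PS = PS)
}

#' Fixed divergence counts of one gene (DN, DS)
#'
#' A codon column contributes to divergence only when all ingroup sequences
#' share one sense codon and all outgroup sequences share a different sense
#' codon (fixed difference); the change is classified by pathway-averaged
#' counting.  Columns polymorphic within either group contribute to
#' polymorphism, not divergence.
#'
#' @param aln A [CodonAlignment-class] with >= 1 outgroup sequence.
#' @return Named numeric `c(DN = ..., DS = ...)`.
#' @export
geneDivergence <- function(aln) {
  if (!aln@valid) stop("invalid gene: ", aln@invalidReason, call. = FALSE)
  if (length(aln@outgroup) < 1L) stop("no outgroup sequences", call. = FALSE)
  cods_in <- lapply(as.character(aln@ingroup), .splitCodons)
  cods_out <- lapply(as.character(aln@outgroup), .splitCodons)
  n_cod <- length(cods_in[[1]])
  DN <- DS <- 0
  for (j in seq_len(n_cod)) {
    ci <- unique(vapply(cods_in, `[[`, "", j))
    co <- unique(vapply(cods_out, `[[`, "", j))
    if (length(ci) != 1L || length(co) != 1L) next
    if (!.isSense(ci) || !.isSense(co) || ci == co) next
    cnt <- pairwiseCodonDiffs(ci, co)
    DN <- DN + cnt[["n"]]; DS <- DS + cnt[["s"]]
  }
  c(DN = DN, DS = DS)
}

#' Per-gene diversity/divergence record
#'
#' Convenience wrapper computing everything [aggregateGenes()] and
#' [bootstrapNull()] need for one gene.
#'
#' @param aln A [CodonAlignment-class].
#' @return A list with `geneID`, `length` (bp), the [geneDiversity()]
#'   fields, and `PN`, `PS`, `DN`, `DS`.
#' @export
geneStats <- function(aln) {
  div <- geneDiversity(aln)
  pol <- genePolymorphism(aln)
  dvg <- if (length(aln@outgroup)) geneDivergence(aln) else c(DN = 0, DS = 0)
  c(list(geneID = aln@geneID,
         length = Biostrings::width(aln@ingroup)[1]),
    div, as.list(pol), as.list(dvg))
}

#' Pool per-gene statistics over partitions
#'
#' Polymorphism and divergence counts are summed within each partition; pi
#' values are pooled length-weighted as (sum of pair-averaged differences) /
#' (sum of pair-averaged sites), matching a concatenated-alignment
#' computation; NI is computed on the pooled counts.
#'
#' @param stats List of [geneStats()] records.
#' @param partition Character vector, one label per gene.
#' @return A data.frame, one row per partition, with pooled `piTotal`,
#'   `piN`, `piS`, `piNpiS`, counts `PN`, `PS`, `DN`, `DS`, ratios and `NI`,
#'   plus `nGenes` and `totalLength`.
#' @export
aggregateGenes <- function(stats, partition) {
  stopifnot(length(stats) == length(partition))
  out <- lapply(split(seq_along(stats), partition), function(idx) {
    gs <- stats[idx]
    num <- function(f) vapply(gs, function(g) as.numeric(g[[f]]), 0)
    PN <- sum(num("PN")); PS <- sum(num("PS"))
    DN <- sum(num("DN")); DS <- sum(num("DS"))
    piN <- sum(num("meanNDiff")) / sum(num("nSites"))
    piS <- sum(num("meanSDiff")) / sum(num("sSites"))
    len <- sum(num("length"))
    mk <- MKTable(PN, PS, DN, DS)
    r <- mkRatios(mk)
    data.frame(partition = partition[idx[1]], nGenes = length(idx),
               totalLength = len,
               piTotal = sum(num("piTotal") * num("length")) / len,
               piN = piN, piS = piS,
               piNpiS = if (piS > 0) piN / piS else NA_real_,
               PN = PN, PS = PS, DN = DN, DS = DS,
               PN_PS = r[["PN_PS"]], DN_DS = r[["DN_DS"]],
               NI = as.numeric(neutralityIndex(mk)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign genes to the drive region or their chromosome
#'
#' Genes on the region's chromosome are assigned to `"region"` when the
#' midpoint of their CDS span lies inside the region, otherwise to the
#' chromosome label; genes straddling a boundary are assigned by midpoint
#' with a note.
#'
#' @param models Gene-model list from [readGeneModels()].
#' @param region A single-range `GRanges` delimiting the drive region.
#' @return Character vector of partition labels, one per gene.
#' @export
genePartition <- function(models, region) {
  stopifnot(length(region) == 1L)
  rchrom <- as.character(GenomicRanges::seqnames(region))
  rstart <- GenomicRanges::start(region); rend <- GenomicRanges::end(region)
  vapply(models, function(m) {
    if (m$chrom != rchrom) return(m$chrom)
    s <- min(GenomicRanges::start(m$cds)); e <- max(GenomicRanges::end(m$cds))
    mid <- (s + e) / 2
    inside <- mid >= rstart && mid <= rend
    straddles <- (s < rstart && e >= rstart) || (s <= rend && e > rend)
    if (straddles)
      .log("gene ", m$geneID, " straddles the region boundary; assigned by midpoint")
    if (inside) "region" else m$chrom
  }, "")
}

#' Gene-resampling bootstrap null for region statistics
#'
#' Each replicate draws `nRegionGenes` genes with replacement from the
#' background set and pools their statistics.  Count statistics (PN, PS,
#' DN, DS) are rescaled by regionLength / (total sampled gene length) so
#' they are comparable to the region's totals; ratio statistics (piN, piS,
#' piN/piS, PN/PS, DN/DS, NI) are left unscaled.  The 95 percent interval is
#' the 2.5/97.5 percentile pair and the empirical two-sided p-value is
#' 2 * min(r, 1 - r) with r = (1 + #\{replicates <= observed\}) / (reps + 1).
#'
#' @param backgroundStats List of [geneStats()] records excluding the
#'   region's genes.
#' @param nRegionGenes Number of genes to draw per replicate.
#' @param regionLength Region sequence length in bp used for rescaling.
#' @param observed Named numeric vector of observed region statistics (any
#'   subset of the statistic names; p-values/intervals are reported for
#'   these).
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return A list, one element per statistic: `observed`, `mean`, `lower`,
#'   `upper`, `p`, `replicates`.
#' @export
bootstrapNull <- function(backgroundStats, nRegionGenes, regionLength,
                          observed = NULL, reps = 1000L, seed = 1L) {
  stopifnot(reps >= 100L, nRegionGenes >= 1L, length(backgroundStats) >= 1L)
  num <- function(gs, f) vapply(gs, function(g) as.numeric(g[[f]]), 0)
  len <- num(backgroundStats, "length")
  PN <- num(backgroundStats, "PN"); PS <- num(backgroundStats, "PS")
  DN <- num(backgroundStats, "DN"); DS <- num(backgroundStats, "DS")
  nd <- num(backgroundStats, "meanNDiff"); sd_ <- num(backgroundStats, "meanSDiff")
  ns <- num(backgroundStats, "nSites"); ss <- num(backgroundStats, "sSites")
  nbg <- length(backgroundStats)

  mat <- .withSeed(seed, {
    t(vapply(seq_len(reps), function(b) {
      i <- sample.int(nbg, nRegionGenes, replace = TRUE)
      L <- sum(len[i])
      sc <- regionLength / L
      pn <- sum(PN[i]); ps <- sum(PS[i]); dn <- sum(DN[i]); ds <- sum(DS[i])
      piN <- sum(nd[i]) / sum(ns[i]); piS <- sum(sd_[i]) / sum(ss[i])
      c(PN = pn * sc, PS = ps * sc, DN = dn * sc, DS = ds * sc,
        piN = piN, piS = piS,
        piNpiS = if (piS > 0) piN / piS else NA_real_,
        PN_PS = if (ps > 0) pn / ps else NA_real_,
        DN_DS = if (ds > 0) dn / ds else NA_real_,
        NI = if (ps > 0 && dn > 0 && ds > 0) (pn / ps) / (dn / ds) else NA_real_)
    }, numeric(10)))
  })

  stat_names <- colnames(mat)
  out <- lapply(stat_names, function(s) {
    v <- mat[, s]
    v_ok <- v[is.finite(v)]
    qs <- quantile(v_ok, c(0.025, 0.975), type = 7, names = FALSE)
    obs <- if (!is.null(observed) && s %in% names(observed))
      as.numeric(observed[[s]]) else NA_real_
    p <- if (is.na(obs)) NA_real_ else {
      r <- (1 + sum(v_ok <= obs)) / (length(v_ok) + 1)
      2 * min(r, 1 - r)
    }
    list(observed = obs, mean = mean(v_ok), lower = qs[1], upper = qs[2],
         p = p, replicates = v)
  })
  names(out) <- stat_names
  out
}

#' Age lower bound from minimum synonymous divergence
#'
#' For each region gene, the synonymous divergence dS to every member of the
#' freely recombining panel is computed and the minimum taken (the closest
#' relative gives a lower bound on the time since recombination stopped);
#' the minimizing partners' synonymous differences and sites are pooled and
#' the age bound is pooled dS / (2 * substitution rate).
#'
#' @param alignments List of [CodonAlignment-class]; `ingroup` holds the
#'   region haplotype(s), `outgroup` the sensitive panel copies.
#' @param ratePerYear Synonymous substitution rate per site per year
#'   (required; no default).
#' @return A list: `perGene` data.frame (geneID, dSmin, partner),
#'   `pooledDS`, `ratePerYear`, `ageYears`.
#' @export
ageLowerBound <- function(alignments, ratePerYear) {
  if (missing(ratePerYear) || !is.numeric(ratePerYear) || ratePerYear <= 0)
    stop("ratePerYear must be a positive substitution rate", call. = FALSE)
  rows <- list(); tot_s <- 0; tot_sites <- 0
  for (aln in alignments) {
    if (!aln@valid) { .log("skipping invalid gene ", aln@geneID); next }
    reg <- as.character(aln@ingroup)
    panel <- as.character(aln@outgroup)
    if (!length(panel)) next
    best <- NULL
    for (r in reg) for (pn in seq_along(panel)) {
      cr <- .splitCodons(r); cp <- .splitCodons(panel[pn])
      ok <- .isSense(cr) & .isSense(cp)
      cr <- cr[ok]; cp <- cp[ok]
      S <- (sum(.ngEnv$siteS[cr]) + sum(.ngEnv$siteS[cp])) / 2
      if (S <= 0) next
      sdiff <- 0
      for (d in which(cr != cp))
        sdiff <- sdiff + pairwiseCodonDiffs(cr[d], cp[d])[["s"]]
      ds <- sdiff / S
      if (is.null(best) || ds < best$ds)
        best <- list(ds = ds, sdiff = sdiff, S = S, partner = pn)
    }
    if (is.null(best)) {
      .log("gene ", aln@geneID, " has no synonymous sites; excluded")
      next
    }
    tot_s <- tot_s + best$sdiff; tot_sites <- tot_sites + best$S
    rows[[length(rows) + 1L]] <- data.frame(geneID = aln@geneID,
                                            dSmin = best$ds,
                                            partner = best$partner,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable genes for the age bound", call. = FALSE)
  pooled <- tot_s / tot_sites
  list(perGene = do.call(rbind, rows), pooledDS = pooled,
       ratePerYear = ratePerYear, ageYears = pooled / (2 * ratePerYear))
}
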