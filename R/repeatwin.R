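#' Fraction of each window covered by repeats
#'
#' Overlapping repeat annotations are merged before counting, so the value
#' is the union coverage and never exceeds 1.
#'
#' @param windows A `GRanges` of windows (e.g. from [fixedWindows()]).
#' @param repeats A `GRanges` of repeat annotations.
#' @return Numeric vector of per-window covered fractions.
#' @export
windowRepeatFraction <- function(windows, repeats) {
  if (length(repeats) == 0L) return(numeric(length(windows)))
  red <- GenomicRanges::reduce(repeats, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(windows, red)
  if (length(hits) == 0L) return(numeric(length(windows)))
  ov <- GenomicRanges::pintersect(windows[S4Vectors::queryHits(hits)],
                                  red[S4Vectors::subjectHits(hits)])
  covered <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out <- numeric(length(windows))
  out[as.integer(names(covered))] <- covered
  out / GenomicRanges::width(windows)
}

#' Classify windows as repeat or non-repeat
#'
#' A window is a "repeat window" iff its repeat fraction strictly exceeds
#' the threshold (default 0.75, so exactly 75 percent is non-repeat).
#'
#' @param fractions Numeric vector of repeat fractions in \[0,1\].
#' @param threshold Classification threshold (default 0.75).
#' @return Factor with levels `repeat`, `non_repeat`.
#' @export
classifyRepeatWindows <- function(fractions, threshold = 0.75) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  factor(ifelse(fractions > threshold, "repeat", "non_repeat"),
         levels = c("repeat", "non_repeat"))
}

#' Per-window GC content
#'
#' GC = (G + C) / (A + C + G + T); N bases are ignored.  Windows with no
#' unambiguous base return NA.
#'
#' @param genome A `DNAStringSet`.
#' @param windows A `GRanges` on the genome's chromosomes.
#' @return Numeric vector of GC fractions.
#' @export
windowGC <- function(genome, windows) {
  chroms <- as.character(GenomicRanges::seqnames(windows))
  if (!all(chroms %in% names(genome)))
    stop("window chromosome(s) absent from genome", call. = FALSE)
  out <- rep(NA_real_, length(windows))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- Biostrings::Views(genome[[chrom]],
                           start = GenomicRanges::start(windows)[idx],
                           end = GenomicRanges::end(windows)[idx])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- freq[, "G"] + freq[, "C"]
    out[idx] <- ifelse(acgt > 0, gc / acgt, NA_real_)
  }
  out
}

#' Percentage of methylated cytosine sites per window
#'
#' A covered cytosine is called methylated when its methylated-read fraction
#' is at least `callThreshold`.  The per-window value is
#' 100 * methylated / covered sites; windows with no covered site are NA and
#' excluded from group means downstream.  `weighted = TRUE` instead returns
#' 100 * sum(methylated reads) / sum(total reads) (counts dialect only).
#'
#' @param track Methylation data.frame from [readMethylation()].
#' @param windows A `GRanges`.
#' @param callThreshold Per-site call threshold on the methylated fraction
#'   (default 0.5).
#' @param weighted Use read-weighted mode instead of site calls.
#' @return Numeric vector of percentages (NA where uncovered).
#' @export
windowMethylation <- function(track, windows, callThreshold = 0.5,
                              weighted = FALSE) {
  covered <- !is.na(track$frac)
  if (!is.na(track$total[1])[1] && any(!is.na(track$total)))
    covered <- covered & !is.na(track$total) & track$total > 0
  tr <- track[covered, , drop = FALSE]
  sites <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$pos, tr$pos))
  hits <- GenomicRanges::findOverlaps(windows, sites)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  out <- rep(NA_real_, length(windows))
  if (!length(hits)) return(out)
  if (weighted) {
    if (all(is.na(tr$total)))
      stop("weighted mode requires the counts dialect", call. = FALSE)
    meth <- tapply(tr$meth[s], q, sum)
    tot <- tapply(tr$total[s], q, sum)
    out[as.integer(names(meth))] <- 100 * meth / tot
  } else {
    called <- tr$frac[s] >= callThreshold
    n_meth <- tapply(called, q, sum)
    n_cov <- tapply(called, q, length)
    out[as.integer(names(n_meth))] <- 100 * n_meth / n_cov
  }
  out
}

#' ChIP fold enrichment over input per window
#'
#' fold = mean immunoprecipitated depth / mean input depth per window;
#' NA where the window's mean input depth is zero.
#'
#' @param ip,input Coverage `GRanges` with `score` (from [readCoverage()]).
#' @param windows A `GRanges`.
#' @param seqlengths Named chromosome lengths (positions without coverage
#'   records count as depth 0).
#' @return Numeric vector of fold enrichments.
#' @export
chipFold <- function(ip, input, windows, seqlengths) {
  chroms <- unique(as.character(GenomicRanges::seqnames(windows)))
  track_chroms <- union(as.character(GenomicRanges::seqnames(ip)),
                        as.character(GenomicRanges::seqnames(input)))
  if (!all(chroms %in% names(seqlengths)))
    stop("window chromosome(s) missing from seqlengths", call. = FALSE)
  if (length(setdiff(track_chroms, names(seqlengths))))
    stop("coverage track chromosome(s) not in seqlengths: mismatched chromosome sets",
         call. = FALSE)
  mean_ip <- .windowMeanDepth(ip, windows, seqlengths)
  mean_in <- .windowMeanDepth(input, windows, seqlengths)
  ifelse(mean_in > 0, mean_ip / mean_in, NA_real_)
}

.windowMeanDepth <- function(track, windows, seqlengths) {
  GenomeInfoDb::seqlevels(track) <-
    union(GenomeInfoDb::seqlevels(track), names(seqlengths))
  GenomeInfoDb::seqlengths(track) <- seqlengths[GenomeInfoDb::seqlevels(track)]
  cov <- GenomicRanges::coverage(track, weight = "score")
  out <- numeric(length(windows))
  chroms <- as.character(GenomicRanges::seqnames(windows))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- IRanges::Views(cov[[chrom]],
                        start = GenomicRanges::start(windows)[idx],
                        end = GenomicRanges::end(windows)[idx])
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}

#' Two-sample comparison of window statistics (Student's t)
#'
#' Pooled-variance two-sample t test (Welch available via `welch = TRUE`),
#' plus each group's mean with a 95 percent normal CI (mean +/- 1.96 SE) for
#' plotting.  Degenerate inputs: zero pooled variance with equal means gives
#' t = 0, p = 1; zero variance with unequal means gives p = 0 and the
#' `degenerate` flag.
#'
#' @param a,b Numeric vectors (NA values dropped; each group needs n >= 2).
#' @param welch Use Welch's unequal-variance test instead.
#' @return A list: `statistic`, `p.value`, `df`, `meanDiff`, `ciA`, `ciB`
#'   (each `c(mean, lower, upper)`), `degenerate`.
#' @export
compareGroups <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 finite values", call. = FALSE)
  ci <- function(x) {
    se <- sd(x) / sqrt(length(x))
    c(mean = mean(x), lower = mean(x) - 1.96 * se, upper = mean(x) + 1.96 * se)
  }
  md <- mean(a) - mean(b)
  if (welch) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(statistic = unname(tt$statistic), p.value = tt$p.value,
                df = unname(tt$parameter), meanDiff = md,
                ciA = ci(a), ciB = ci(b), degenerate = FALSE))
  }
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (sp2 <= 0) {
    if (md == 0) return(list(statistic = 0, p.value = 1, df = df, meanDiff = 0,
                             ciA = ci(a), ciB = ci(b), degenerate = FALSE))
    return(list(statistic = sign(md) * Inf, p.value = 0, df = df, meanDiff = md,
                ciA = ci(a), ciB = ci(b), degenerate = TRUE))
  }
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- md / se
  list(statistic = tstat, p.value = 2 * pt(-abs(tstat), df), df = df,
       meanDiff = md, ciA = ci(a), ciB = ci(b), degenerate = FALSE)
}

#' Repeat-family enrichment in a region (one-sided binomial tests)
#'
#' For each family: k = family bp inside the region, n = region length,
#' p0 = family bp genome-wide / genome length; the p-value is the upper-tail
#' binomial probability P(X >= k | n, p0), significance is Bonferroni
#' corrected across the families tested, and fold = (k/n)/p0.  `unit =
#' "count"` uses annotation counts as trials instead of base pairs.
#'
#' @param regionRepeats,genomeRepeats `GRanges` with a `family` mcol (the
#'   region's annotations must be a subset of the genome's).
#' @param regionLength,genomeLength Region and genome sizes in bp (for
#'   `unit = "count"`, total annotation counts are used instead).
#' @param alpha Family-wise significance level before correction (0.05).
#' @param unit `"bp"` (default) or `"count"`.
#' @return A data.frame: `family`, `regionCount`, `genomeCount`,
#'   `expectedFraction`, `fold`, `pValue`, `significant`.
#' @export
familyEnrichment <- function(regionRepeats, genomeRepeats, regionLength,
                             genomeLength, alpha = 0.05, unit = c("bp", "count")) {
  unit <- match.arg(unit)
  fam_amount <- function(gr) {
    if (!length(gr)) return(setNames(numeric(0), character(0)))
    if (unit == "bp") {
      per <- lapply(split(gr, gr$family), function(x)
        sum(GenomicRanges::width(GenomicRanges::reduce(x, ignore.strand = TRUE))))
      unlist(per)
    } else {
      tab <- table(gr$family)
      setNames(as.numeric(tab), names(tab))
    }
  }
  reg <- fam_amount(regionRepeats)
  gen <- fam_amount(genomeRepeats)
  if (unit == "count") {
    regionLength <- sum(reg); genomeLength <- sum(gen)
  }
  fams <- names(gen)
  orphan <- setdiff(names(reg), fams)
  if (length(orphan))
    warning("family absent genome-wide, skipped: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  n_tested <- length(fams)
  res <- lapply(fams, function(f) {
    k <- if (f %in% names(reg)) reg[[f]] else 0
    p0 <- gen[[f]] / genomeLength
    p <- stats::pbinom(k - 1, size = round(regionLength), prob = p0,
                       lower.tail = FALSE)
    data.frame(family = f, regionCount = k, genomeCount = gen[[f]],
               expectedFraction = p0,
               fold = (k / regionLength) / p0,
               pValue = p,
               significant = p < alpha / n_tested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  attr(out, "bonferroniThreshold") <- alpha / n_tested
  out
}

#' Region statistic versus genome-wide sliding-window confidence interval
#'
#' Slides a window of the region's own size across the genome (the caller
#' supplies the per-window statistic), and reports the genome mean with an
#' empirical 95 percent interval (2.5th / 97.5th percentiles, linear
#' interpolation) and whether the region value falls outside it.
#'
#' @param windowValues Per-sliding-window statistic (NA dropped).
#' @param regionValue The region's value of the same statistic.
#' @return A list: `regionValue`, `genomeMean`, `lower`, `upper`,
#'   `outside`, `nWindows`, plus a `method` note in `meta`.
#' @export
regionVsGenomeCI <- function(windowValues, regionValue) {
  v <- windowValues[is.finite(windowValues)]
  if (length(v) < 20L)
    stop("need at least 20 genome windows; use a smaller step size", call. = FALSE)
  qs <- quantile(v, c(0.025, 0.975), type = 7, names = FALSE)
  list(regionValue = regionValue, genomeMean = mean(v),
       lower = qs[1], upper = qs[2],
       outside = regionValue < qs[1] || regionValue > qs[2],
       nWindows = length(v),
       meta = "empirical percentile CI (2.5/97.5, linear interpolation)")
}
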