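test_that("window repeat fraction is union coverage", {
  w <- fixedWindows(6000, 2000, 2000)
  reps <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    c(1, 2001, 2401), c(2000, 2500, 3000)),
    family = "f", class = "c")
  fr <- windowRepeatFraction(w, reps)
  expect_equal(fr[1], 1.0)            # fully covered window
  expect_equal(fr[2], 0.5)            # [2001,2500] u [2401,3000] = 1000 bp
  expect_equal(fr[3], 0.0)

  ## invariant to order and to splitting annotations into abutting pieces
  reps_shuffled <- reps[c(3, 1, 2)]
  split_up <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    c(1, 1001, 2001, 2401, 2601), c(1000, 2000, 2400, 2600, 3000)),
    family = "f", class = "c")
  expect_equal(windowRepeatFraction(w, reps_shuffled), fr)
  expect_equal(windowRepeatFraction(w, split_up), fr)
  expect_true(all(fr <= 1))
})

test_that("repeat-window classification uses a strict 75% threshold", {
  cls <- classifyRepeatWindows(c(0.76, 0.75, 0.8, 0.1, 0.9))
  expect_identical(as.character(cls),
                   c("repeat", "non_repeat", "repeat", "non_repeat", "repeat"))
})

test_that("window GC, methylation percentage and ChIP fold are computed", {
  genome <- Biostrings::DNAStringSet(c(chr = paste(rep("ATGC", 500),
                                                   collapse = "")))
  w <- fixedWindows(2000, 2000, 2000, chrom = "chr")
  expect_equal(windowGC(genome, w), 0.5)

  ## 10 covered cytosines, 4 with methylated fraction >= 0.5 -> 40 %
  track <- data.frame(chrom = "chr", pos = seq(10, 100, by = 10),
                      frac = c(.9, .8, .55, .5, .4, .3, .2, .1, 0, 0),
                      meth = NA_real_, total = NA_real_)
  expect_equal(windowMethylation(track, w), 40)
  ## weighted mode needs the counts dialect
  expect_error(windowMethylation(track, w, weighted = TRUE), "counts dialect")
  track2 <- data.frame(chrom = "chr", pos = c(10, 20),
                       frac = c(1, 0), meth = c(8, 0), total = c(8, 2))
  expect_equal(windowMethylation(track2, w, weighted = TRUE), 80)

  ## uniform IP depth 30 over input depth 10 -> fold 3
  sl <- c(chr = 2000L)
  ip <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 2000), score = 30)
  input <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 2000), score = 10)
  expect_equal(chipFold(ip, input, w, sl), 3.0)
  ## identical tracks -> fold 1 everywhere
  expect_equal(chipFold(ip, ip, fixedWindows(2000, 500, 500, "chr"), sl),
               rep(1, 4))
  ## zero input -> undefined
  zero <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 2000), score = 0)
  expect_true(is.na(chipFold(ip, zero, w, sl)))
})

test_that("pooled t test matches hand computation and stats::t.test", {
  cg <- compareGroups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cg$statistic, -1.2247449, tolerance = 1e-6)
  expect_equal(cg$p.value, 0.2878641, tolerance = 1e-6)
  ## independent check against the reference implementation
  tt <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(cg$statistic, unname(tt$statistic))
  expect_equal(cg$p.value, tt$p.value)

  same <- compareGroups(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  ident <- compareGroups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$p.value, 1)
  expect_false(ident$degenerate)

  deg <- compareGroups(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)

  ## Welch flag defers to the reference implementation
  set.seed(2); a <- rnorm(10); b <- rnorm(12, sd = 3)
  cw <- compareGroups(a, b, welch = TRUE)
  tw <- t.test(a, b)
  expect_equal(cw$p.value, tw$p.value)
})

test_that("group separation is detected on planted GC contrasts", {
  ## power check: repeat windows at GC ~0.30, non-repeat at ~0.50
  set.seed(10)
  gc_rep <- rnorm(100, 0.30, 0.03)
  gc_non <- rnorm(100, 0.50, 0.03)
  cg <- compareGroups(gc_rep, gc_non)
  expect_lt(cg$p.value, 1e-3)
  expect_lt(cg$ciA[["upper"]], cg$ciB[["lower"]])
})

test_that("family enrichment p-values are exact binomial tails", {
  ## closed form: k = n = 10, p0 = 20/40 = 0.5 -> P(X >= 10) = 0.5^10
  region <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 10),
                                   family = "famA", class = "c")
  genome <- GenomicRanges::GRanges("chr",
                                   IRanges::IRanges(c(1, 21, 31), c(10, 30, 36)),
                                   family = c("famA", "famA", "famB"),
                                   class = "c")
  res <- familyEnrichment(region, genome, regionLength = 10,
                          genomeLength = 40)
  rowA <- res[res$family == "famA", ]
  expect_equal(rowA$pValue, 0.5^10, tolerance = 1e-12)
  expect_equal(rowA$fold, 2)            # (10/10)/(20/40)
  ## k = 0 -> p = 1
  rowB <- res[res$family == "famB", ]
  expect_equal(rowB$pValue, 1)
  expect_identical(attr(res, "bonferroniThreshold"), 0.05 / 2)

  ## exhaustive-summation oracle for n <= 20
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:20, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    ours <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    expect_equal(ours, bruteBinomUpper(k, n, p0), tolerance = 1e-12)
  }

  ## family absent genome-wide is skipped with a warning
  region2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 10),
                                    family = "ghost", class = "c")
  expect_warning(familyEnrichment(region2, genome, 10, 1020), "ghost")
})

test_that("region-vs-genome CI uses empirical percentiles", {
  const <- rep(0.16, 30)
  ci <- regionVsGenomeCI(const, 0.42)
  expect_equal(ci$lower, 0.16)
  expect_equal(ci$upper, 0.16)
  expect_true(ci$outside)

  ci2 <- regionVsGenomeCI(1:100, 50)
  expect_equal(ci2$lower, 3.475)
  expect_equal(ci2$upper, 97.525)
  expect_false(ci2$outside)

  ci3 <- regionVsGenomeCI(1:100, mean(1:100))
  expect_false(ci3$outside)

  expect_error(regionVsGenomeCI(1:10, 5), "smaller step")
})
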