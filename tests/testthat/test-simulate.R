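smallSimParams <- function(seed, ...) {
  simulationParams(seed = seed, chromosomes = c(chr1 = 30000L, chr3 = 60000L),
                   regionChrom = "chr3", regionStart = 15001L,
                   regionEnd = 50000L, nSensitive = 4L, nKillerA = 3L,
                   nKillerB = 1L, nOutgroup = 2L, thetaWithin = 0.003,
                   killerSplit = 0.015, outgroupDepth = 0.04,
                   nRegionGenes = 4L, nBackgroundGenes = 6L,
                   nRepeatClusters = 4L, ...)
}

test_that("the same seed reproduces byte-identical output files", {
  p <- smallSimParams(seed = 21)
  d1 <- tempfile("simA"); d2 <- tempfile("simB")
  s1 <- simulateDriveData(p, dir = d1)
  s2 <- simulateDriveData(p, dir = d2)
  for (nm in names(s1$files))
    expect_identical(readLines(s1$files[[nm]]), readLines(s2$files[[nm]]),
                     label = paste("file", nm))
  ## a different seed changes the data
  s3 <- simulateDriveData(smallSimParams(seed = 22))
  expect_false(identical(positions(s1$vm, "chr3"), positions(s3$vm, "chr3")))
})

test_that("emitted files parse cleanly through the package readers", {
  p <- smallSimParams(seed = 23, missingRate = 0.001)
  dir <- tempfile("simC")
  sim <- simulateDriveData(p, dir = dir)
  sl <- setNames(Biostrings::width(sim$genome), names(sim$genome))

  g <- readGenome(sim$files$fasta)
  expect_identical(as.character(g), as.character(sim$genome))

  vm <- readVariants(sim$files$vcf)
  expect_identical(sampleNames(vm), sampleNames(sim$vm))
  for (ch in chromNames(vm)) {
    expect_identical(positions(vm, ch), positions(sim$vm, ch))
    expect_identical(unname(genotypes(vm, ch)), unname(genotypes(sim$vm, ch)))
  }

  reps <- readRepeatMasker(sim$files$repeats, seqlengths = sl)
  expect_identical(length(reps), length(sim$repeats))
  expect_setequal(reps$family, sim$repeats$family)

  models <- readGeneModels(sim$files$gff, seqlengths = sl)
  expect_identical(sort(names(models)), sort(names(sim$models)))
  expect_true(all(vapply(models, `[[`, TRUE, "valid")))

  meth <- readMethylation(sim$files$methylation, seqlengths = sl)
  expect_identical(nrow(meth), nrow(sim$methylation))
  expect_true(all(meth$meth <= meth$total))

  cov <- readCoverage(sim$files$ip, seqlengths = sl)
  expect_identical(length(cov), length(sim$ipCoverage))

  truth <- jsonlite::read_json(sim$files$truth, simplifyVector = TRUE)
  expect_identical(truth$region$chrom, "chr3")
  expect_identical(nrow(truth$genes), nrow(sim$truth$genes))
})

test_that("repeat clusters are GC-poor, methylated and ChIP-enriched", {
  gc_gap <- numeric(0)
  for (seed in 41:45) {
    sim <- simulateDriveData(smallSimParams(seed = seed))
    w <- fixedWindows(60000L, 2000L, 2000L, chrom = "chr3")
    fr <- windowRepeatFraction(w, sim$repeats)
    cls <- classifyRepeatWindows(fr)
    gc <- windowGC(sim$genome, w)
    skip_if(sum(cls == "repeat") < 2)
    gc_gap <- c(gc_gap, mean(gc[cls == "non_repeat"]) -
                  mean(gc[cls == "repeat"]))
    meth <- windowMethylation(sim$methylation, w)
    expect_gt(mean(meth[cls == "repeat"], na.rm = TRUE),
              mean(meth[cls == "non_repeat"], na.rm = TRUE))
    sl <- setNames(Biostrings::width(sim$genome), names(sim$genome))
    fold <- chipFold(sim$ipCoverage, sim$inputCoverage, w, sl)
    expect_gt(mean(fold[cls == "repeat"], na.rm = TRUE), 2)
  }
  ## GC gap close to the configured 0.50 - 0.30
  expect_true(all(gc_gap > 0.1))
})

test_that("pairwise distance between sensitives matches 2*theta (Poisson)", {
  p <- simulationParams(seed = 55, chromosomes = c(chrA = 100000L),
                        regionChrom = "chrA", regionStart = 1L,
                        regionEnd = 99999L, nSensitive = 6L, nKillerA = 2L,
                        nKillerB = 0L, nOutgroup = 2L, thetaWithin = 0.004,
                        killerSplit = 0, outgroupDepth = 0.03,
                        nRegionGenes = 0L, nBackgroundGenes = 0L,
                        nRepeatClusters = 0L)
  sim <- simulateDriveData(p)
  g <- genotypes(sim$vm, "chrA")
  L <- 100000
  n_diff <- sum(g["sens1", ] != g["sens2", ])
  expected <- 2 * 0.004 * L
  expect_lt(abs(n_diff - expected), 3 * sqrt(expected))
})

test_that("omega = 0 plants purely synonymous coding variation", {
  p <- smallSimParams(seed = 61, omega = 0)
  sim <- simulateDriveData(p)
  ing <- c(sim$samples$sensitive, sim$samples$focal, sim$samples$anchor)
  alns <- buildCodonAlignments(sim$genome, sim$vm, sim$models,
                               ingroup = ing,
                               outgroup = sim$samples$outgroup)
  for (aln in alns) {
    st <- geneStats(aln)
    expect_equal(st$piN, 0)
    expect_equal(unname(st$PN), 0)
    expect_equal(unname(st$DN), 0)
  }
})

test_that("planted per-gene counts are recovered exactly from the VCF", {
  for (seed in c(71, 72)) {
    p <- smallSimParams(seed = seed, omega = 0.3)
    sim <- simulateDriveData(p)
    ing <- c(sim$samples$sensitive, sim$samples$focal, sim$samples$anchor)
    alns <- buildCodonAlignments(sim$genome, sim$vm, sim$models, ing,
                                 sim$samples$outgroup)
    tg <- sim$truth$genes
    for (gid in tg$geneID) {
      pol <- genePolymorphism(alns[[gid]])
      dvg <- geneDivergence(alns[[gid]])
      r <- tg[tg$geneID == gid, ]
      expect_equal(unname(pol["PN"]), r$polyN, label = paste(gid, "PN"))
      expect_equal(unname(pol["PS"]), r$polyS, label = paste(gid, "PS"))
      expect_equal(unname(dvg["DN"]), r$divN, label = paste(gid, "DN"))
      expect_equal(unname(dvg["DS"]), r$divS, label = paste(gid, "DS"))
    }
  }
})

test_that("zero killer split leaves no monophyly signal above chance", {
  sim <- simulateDriveData(leanScanParams(seed = 81, killerSplit = 0))
  sc <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                       outgroup = sim$samples$outgroup, reps = 0, seed = 1)
  full <- paste(sort(sim$samples$focal), collapse = ",")
  expect_lt(mean(sc$calls$category == full), 0.2)
})

test_that("published MK count fixtures are immutable and validated", {
  f1 <- skMKCounts()
  f2 <- skMKCounts()
  expect_identical(lapply(f1, mkCounts), lapply(f2, mkCounts))
  expect_identical(unname(mkCounts(f1$SkRegion)), c(770, 1499, 2985, 7360))
  expect_identical(unname(mkCounts(f1$Total)),
                   c(58830, 153013, 59077, 132834))
  expect_named(f1, c("Total", "Chr1", "Chr2", "Chr3", "Chr7", "SkRegion"))
})

test_that("tract validation respects strict mode", {
  expect_error(simulationParams(tracts = list(list(sample = "kA1",
                                                   start = 1L, end = 50L))),
               "outside region")
  expect_warning(simulationParams(strict = FALSE,
                                  tracts = list(list(sample = "kA1",
                                                     start = 1L, end = 50L))),
                 "outside region")
})
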