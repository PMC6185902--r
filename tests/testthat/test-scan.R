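test_that("scan reports full-focal monophyly when no recombination is planted", {
  sim <- simulateDriveData(leanScanParams(seed = 301))
  sc <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                       outgroup = sim$samples$outgroup, reps = 0, seed = 1)
  full <- paste(sort(sim$samples$focal), collapse = ",")
  expect_gt(length(sc$calls), 80)
  expect_gte(mean(sc$calls$category == full), 0.99)
})

test_that("a planted introgression tract flips the category over the tract", {
  tract <- list(sample = "kA4", start = 20001L, end = 32000L)
  sim <- simulateDriveData(leanScanParams(seed = 302, tracts = list(tract)))
  sc <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                       outgroup = sim$samples$outgroup, reps = 0, seed = 1)
  reduced <- paste(sort(setdiff(sim$samples$focal, "kA4")), collapse = ",")
  ## truth: windows whose midpoint lies in the tract (majority of the
  ## window's signal is erased there)
  mid <- (GenomicRanges::start(sc$calls) + GenomicRanges::end(sc$calls)) / 2
  true_idx <- which(mid >= tract$start & mid <= tract$end)
  det_idx <- which(sc$calls$category == reduced)
  expect_gt(length(det_idx), 0)
  ## every interior window (a window away from the boundary mixture zone)
  ## flips to the reduced category, and nothing flips outside the tract
  core <- true_idx[-c(1, 2, length(true_idx) - 1, length(true_idx))]
  expect_true(all(core %in% det_idx))
  expect_true(all(det_idx >= min(true_idx) - 1 & det_idx <= max(true_idx) + 1))
  ## boundary windows resolve within the mixing zone; the distributional
  ## +/-1-window guarantee is asserted over 100 replicates in the
  ## acceptance suite
  expect_lte(abs(min(det_idx) - min(true_idx)), 2)
  expect_lte(abs(max(det_idx) - max(true_idx)), 2)
})

test_that("bin proportions sum to one and bin=1 gives indicators", {
  sim <- simulateDriveData(leanScanParams(seed = 303))
  sc <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                       outgroup = sim$samples$outgroup, reps = 0, bin = 50,
                       seed = 1)
  sums <- tapply(sc$bins$proportion, sc$bins$bin, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ## final partial bin reported with its actual size
  n_win <- length(sc$calls)
  expect_identical(max(sc$bins$windowEnd), n_win)
  last <- sc$bins[sc$bins$bin == max(sc$bins$bin), ]
  expect_equal(unique(last$size), n_win - (max(sc$bins$bin) - 1L) * 50L)

  sc1 <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                        outgroup = sim$samples$outgroup, reps = 0, bin = 1,
                        seed = 1)
  expect_true(all(sc1$bins$proportion == 1))
  expect_identical(nrow(sc1$bins), length(sc1$calls))
  expect_identical(sc1$bins$category, sc1$calls$category)
})

test_that("joint scans with an anchor report which focal ids join it", {
  ## anchored category per window comes from the killer-B anchor sample
  p <- simulationParams(seed = 304, chromosomes = c(chrR = 30000L),
                        regionChrom = "chrR", regionStart = 1L,
                        regionEnd = 30000L, nSensitive = 5L, nKillerA = 3L,
                        nKillerB = 1L, nOutgroup = 3L, thetaWithin = 0.003,
                        killerSplit = 0.02, outgroupDepth = 0.05,
                        nRegionGenes = 0L, nBackgroundGenes = 0L,
                        nRepeatClusters = 0L)
  sim <- simulateDriveData(p)
  sc <- scanChromosome(sim$vm, "chrR", focal = sim$samples$focal,
                       outgroup = sim$samples$outgroup, reps = 0,
                       anchor = "kB1", seed = 1)
  ## killer B evolves on its own branch: no strong joint monophyly expected
  expect_gt(mean(sc$calls$category == ""), 0.5)
  expect_true(all(sc$calls$anchorPresent == (sc$calls$category != "")))
})

test_that("pairwise divergence windows match a naive recount", {
  set.seed(11)
  S <- 400
  bases <- matrix(sample(c("A", "C", "G", "T"), 3 * S, replace = TRUE),
                  nrow = 3, dimnames = list(c("x", "y", "z"), NULL))
  pos <- sort(sample.int(50000L, S))
  vm <- vmFromBases(bases, pos, chrom = "c1")
  ## identical samples -> all zero
  vm0 <- vmFromBases(rbind(x = bases[1, ], y = bases[1, ], z = bases[3, ]),
                     pos, chrom = "c1")
  d0 <- pairwiseDivergenceScan(vm0, "c1", "x", "y", 10000L, 2000L, 50000L)
  expect_true(all(d0$divergence == 0))

  d <- pairwiseDivergenceScan(vm, "c1", "x", "y", 10000L, 2000L, 50000L)
  ## naive per-window rescan oracle
  g <- genotypes(vm, "c1")
  for (k in seq_along(d)) {
    s <- GenomicRanges::start(d)[k]; e <- GenomicRanges::end(d)[k]
    in_win <- which(pos >= s & pos <= e)
    expect_identical(d$nDiff[k],
                     sum(g["x", in_win] != g["y", in_win]))
  }
  expect_equal(d$divergence, d$nDiff / 10000)
})
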