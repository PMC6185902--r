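test_that("NG86 site counts follow the per-position synonymous fractions", {
  expect_equal(ng86SiteCounts("TTT"), c(N = 8 / 3, S = 1 / 3))
  expect_equal(ng86SiteCounts("ATG"), c(N = 3, S = 0))
  ## every sense codon: N + S = 3 under the stop-excluded-denominator rule
  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  for (cod in sense) {
    cnt <- ng86SiteCounts(cod)
    expect_equal(unname(cnt["N"] + cnt["S"]), 3)
    expect_gte(cnt[["S"]], 0)
  }
  expect_error(ng86SiteCounts("TAA"), "sense codon")
})

test_that("pathway-averaged codon differences sum to the Hamming distance", {
  expect_equal(pairwiseCodonDiffs("TTT", "TTA"), c(n = 1, s = 0))
  expect_equal(pairwiseCodonDiffs("TTT", "GTA"), c(n = 1.5, s = 0.5))
  expect_equal(pairwiseCodonDiffs("AAA", "AAA"), c(n = 0, s = 0))
  ## synonymous single step
  expect_equal(pairwiseCodonDiffs("TTT", "TTC"), c(n = 0, s = 1))
})

test_that("gene diversity recovers planted per-pair values", {
  ## identical sequences: all pi zero
  a0 <- alnFromStrings(c(x = "ATGAAATTTTAA", y = "ATGAAATTTTAA"))
  d0 <- geneDiversity(a0)
  expect_equal(d0$piTotal, 0)
  expect_equal(d0$piN, 0)
  expect_equal(d0$piS, 0)

  ## one synonymous change in a 3-codon comparable stretch:
  ## TTT -> TTC is synonymous
  a1 <- alnFromStrings(c(x = "ATGAAATTTTAA", y = "ATGAAATTCTAA"))
  d1 <- geneDiversity(a1)
  expect_equal(d1$piN, 0)
  ## S sites over the 3 comparable sense codons (terminal TAA excluded)
  s_sites <- sum(ng86SiteCounts("ATG")["S"], ng86SiteCounts("AAA")["S"],
                 ng86SiteCounts("TTT")["S"] / 2,
                 ng86SiteCounts("TTC")["S"] / 2)
  expect_equal(d1$piS, 1 / s_sites)

  ## three sequences: pi is the mean of the three pairwise values
  a3 <- alnFromStrings(c(x = "ATGAAATTTTAA", y = "ATGAAATTCTAA",
                         z = "ATGAAATTTTAA"))
  d3 <- geneDiversity(a3)
  expect_equal(d3$piS, (1 / s_sites + 0 + 1 / s_sites) / 3)

  expect_error(geneDiversity(alnFromStrings(c(x = "ATGAAATTTTAA"))),
               ">= 2 ingroup")
})

test_that("divergence counts only fixed differences", {
  ## ingroup all TTT, outgroup all TTC: one synonymous fixed difference
  a <- alnFromStrings(c(i1 = "ATGTTTTAA", i2 = "ATGTTTTAA"),
                      c(o1 = "ATGTTCTAA", o2 = "ATGTTCTAA"))
  expect_equal(geneDivergence(a), c(DN = 0, DS = 1))

  ## ingroup polymorphic at the codon: no D contribution
  b <- alnFromStrings(c(i1 = "ATGTTTTAA", i2 = "ATGTTCTAA"),
                      c(o1 = "ATGTTATAA"))
  expect_equal(geneDivergence(b), c(DN = 0, DS = 0))
  ## but it does contribute to polymorphism
  expect_equal(genePolymorphism(b), c(PN = 0, PS = 1))

  ## identical ingroup and outgroup: nothing
  c0 <- alnFromStrings(c(i1 = "ATGTTTTAA"), c(o1 = "ATGTTTTAA"))
  expect_equal(geneDivergence(c0), c(DN = 0, DS = 0))
})

test_that("aggregation pools counts and matches concatenated alignments", {
  mk1 <- MKTable(1, 2, 3, 4)
  mk2 <- MKTable(2, 2, 3, 4)
  expect_equal(unname(mkCounts(mk1) + mkCounts(mk2)), c(3, 4, 6, 8))

  ## two genes, two ingroup + one outgroup sequence each (no terminal stop
  ## so the concatenation remains a clean ORF)
  g1_in <- c(a = "ATGAAATTTACT", b = "ATGAAATTCACT")
  g1_out <- c(o = "ATGAAATTAACT")
  g2_in <- c(a = "ATGGGGCCCGAT", b = "ATGGGACCCGAT")
  g2_out <- c(o = "ATGGGGCCGGAT")
  alns <- list(alnFromStrings(g1_in, g1_out, id = "g1"),
               alnFromStrings(g2_in, g2_out, id = "g2"))
  st <- lapply(alns, geneStats)
  agg <- aggregateGenes(st, c("p", "p"))
  ## concatenation oracle
  cat_aln <- alnFromStrings(c(a = paste0(g1_in["a"], g2_in["a"]),
                              b = paste0(g1_in["b"], g2_in["b"])),
                            c(o = paste0(g1_out["o"], g2_out["o"])))
  cat_div <- geneDiversity(cat_aln)
  expect_equal(agg$piS, cat_div$piS)
  expect_equal(agg$piN, cat_div$piN)
  cat_pol <- genePolymorphism(cat_aln)
  cat_dvg <- geneDivergence(cat_aln)
  expect_equal(agg$PN, unname(cat_pol["PN"]))
  expect_equal(agg$PS, unname(cat_pol["PS"]))
  expect_equal(agg$DN, unname(cat_dvg["DN"]))
  expect_equal(agg$DS, unname(cat_dvg["DS"]))

  ## single-gene partition equals the gene's own stats
  agg1 <- aggregateGenes(st[1], "solo")
  expect_equal(agg1$PN, unname(genePolymorphism(alns[[1]])["PN"]))
})

test_that("the neutrality index reproduces published ratio arithmetic", {
  expect_equal(round(neutralityIndex(MKTable(770, 1499, 2985, 7360)), 2), 1.27)
  expect_equal(round(neutralityIndex(MKTable(58830, 153013, 59077, 132834)), 2),
               0.86)
  expect_equal(neutralityIndex(MKTable(1, 1, 1, 1)), 1.0)
  expect_true(is.na(neutralityIndex(MKTable(1, 0, 1, 1))))
  expect_identical(attr(neutralityIndex(MKTable(1, 0, 1, 1)), "reason"),
                   "PS == 0")
  expect_true(is.na(neutralityIndex(MKTable(1, 1, 0, 1))))
})

test_that("bootstrap null behaves on degenerate and bulk cases", {
  ## identical background genes: zero-width interval at the common value
  gene <- list(geneID = "g", length = 300, PN = 2, PS = 4, DN = 3, DS = 6,
               meanNDiff = 2, meanSDiff = 4, nSites = 200, sSites = 100,
               piTotal = 0.01, piN = 0.01, piS = 0.04)
  bg <- rep(list(gene), 10)
  bn <- bootstrapNull(bg, nRegionGenes = 3, regionLength = 900,
                      observed = c(NI = 1), reps = 100, seed = 1)
  expect_equal(bn$NI$lower, bn$NI$upper)
  expect_equal(bn$NI$lower, 1)      # (2/4)/(3/6) = 1
  expect_equal(bn$PS$lower, bn$PS$upper)
  expect_equal(bn$PS$lower, 12)     # 3 genes x 4, rescaled by 900/900

  ## observed inside the null bulk: p near 1
  set.seed(20)
  bg2 <- lapply(1:40, function(i) {
    L <- 900
    list(geneID = paste0("g", i), length = L,
         PN = rpois(1, 9), PS = rpois(1, 18),
         DN = rpois(1, 9), DS = rpois(1, 18),
         meanNDiff = rpois(1, 9), meanSDiff = rpois(1, 18),
         nSites = L * 0.75, sSites = L * 0.25,
         piTotal = 0.01, piN = 0.01, piS = 0.04)
  })
  bn2 <- bootstrapNull(bg2, nRegionGenes = 10, regionLength = 9000,
                       observed = c(NI = 1), reps = 200, seed = 2)
  expect_gt(bn2$NI$p, 0.2)
  expect_true(bn2$NI$lower <= 1 && 1 <= bn2$NI$upper)
  expect_error(bootstrapNull(bg2, 10, 9000, reps = 10), "reps")
})

test_that("the age bound is pooled minimum dS over twice the rate", {
  ## all panel members identical to the region copy -> age 0
  a0 <- alnFromStrings(c(r = "ATGAAATTTTAA"),
                       c(p1 = "ATGAAATTTTAA", p2 = "ATGAAATTTTAA"),
                       id = "gA")
  age0 <- ageLowerBound(list(a0), ratePerYear = 1e-8)
  expect_equal(age0$ageYears, 0)

  ## closed form: pooled dS / (2 mu)
  ## TTT->TTC synonymous: dS = 1 / S_sites
  a1 <- alnFromStrings(c(r = "ATGAAATTTTAA"),
                       c(p1 = "ATGAAATTCTAA"), id = "gB")
  age1 <- ageLowerBound(list(a1), ratePerYear = 1e-8)
  expect_equal(age1$ageYears, age1$pooledDS / (2e-8))
  expect_gt(age1$ageYears, 0)

  ## adding a closer panel member can only decrease the estimate
  a2 <- alnFromStrings(c(r = "ATGAAATTTTAA"),
                       c(p1 = "ATGAAATTCTAA", p2 = "ATGAAATTTTAA"), id = "gB")
  age2 <- ageLowerBound(list(a2), ratePerYear = 1e-8)
  expect_lte(age2$ageYears, age1$ageYears)
  expect_equal(age2$ageYears, 0)

  expect_error(ageLowerBound(list(a1)), "ratePerYear")
})

test_that("haplotype de-duplication collapses identical ingroup sequences", {
  a <- alnFromStrings(c(x = "ATGAAATTTTAA", y = "ATGAAATTTTAA",
                        z = "ATGAAATTCTAA"))
  dd <- dedupHaplotypes(a)
  expect_length(dd@ingroup, 2L)
  expect_setequal(as.character(dd@ingroup),
                  c("ATGAAATTTTAA", "ATGAAATTCTAA"))
})
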