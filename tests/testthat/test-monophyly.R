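test_that("rooting places the root on the outgroup stem", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,OUT:1):1);")
  r <- rootOnOutgroup(tr, "OUT")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  tipsets <- lapply(kids, function(k) {
    if (k <= length(r$tip.label)) r$tip.label[k]
    else ape::extract.clade(r, k)$tip.label
  })
  expect_true(any(vapply(tipsets, function(s) identical(s, "OUT"), TRUE)))

  ## an outgroup cherry roots on its stem
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,(O1:1,O2:1):2,C:1);")
  r2 <- rootOnOutgroup(tr2, c("O1", "O2"))
  og_node <- ape::getMRCA(r2, c("O1", "O2"))
  expect_setequal(ape::extract.clade(r2, og_node)$tip.label, c("O1", "O2"))

  ## non-monophyletic outgroup falls back with a warning
  tr3 <- ape::read.tree(text = "((A:1,O1:1):1,(B:1,O2:1):1,C:1);")
  expect_warning(r3 <- rootOnOutgroup(tr3, c("O1", "O2")), "not monophyletic")
  expect_true(ape::is.rooted(r3))

  expect_error(rootOnOutgroup(tr, "nope"), "not in tree")
})

test_that("classification finds the largest exclusively-focal clade", {
  focal <- c("F1", "F2", "F3", "F4")
  t1 <- ape::read.tree(text = "(((F1,F2),(F3,F4)),(S1,S2),OUT);")
  r1 <- rootOnOutgroup(ape::unroot(t1), "OUT")
  expect_identical(classifyGrouping(r1, focal), c("F1", "F2", "F3", "F4"))

  ## F4 nested among sensitives: only (F1,F2,F3) group
  t2 <- ape::read.tree(text = "(((F1,F2),F3),(S1,(F4,S2)),OUT);")
  r2 <- rootOnOutgroup(ape::unroot(t2), "OUT")
  expect_identical(classifyGrouping(r2, focal), c("F1", "F2", "F3"))

  ## anchored: smallest admissible clade above the anchor
  t3 <- ape::read.tree(text = "(((K,F2),(F1,F3)),(S1,S2),OUT);")
  r3 <- rootOnOutgroup(ape::unroot(t3), "OUT")
  expect_identical(classifyGrouping(r3, focal = c("F1", "F2", "F3"),
                                    anchor = "K"), "F2")
  ## anchor nested among non-focal leaves: empty category
  t4 <- ape::read.tree(text = "(((K,S1),F2),(F1,S2),OUT);")
  r4 <- rootOnOutgroup(ape::unroot(t4), "OUT")
  expect_identical(classifyGrouping(r4, focal = c("F1", "F2"), anchor = "K"),
                   character(0))

  expect_error(classifyGrouping(ape::unroot(t1), focal), "rooted")
})

test_that("classification agrees with brute-force clade enumeration", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    tips <- tr$tip.label
    focal <- sample(tips, sample(2:(n - 1), 1))
    expect_identical(classifyGrouping(tr, focal), sort(bruteClassify(tr, focal)))
    anchor <- sample(setdiff(tips, focal), 1)
    expect_identical(classifyGrouping(tr, setdiff(focal, anchor), anchor = anchor),
                     bruteClassifyAnchor(tr, setdiff(focal, anchor), anchor))
  }
})

test_that("bootstrap support is ~1 for a clade fixed at every site", {
  ## focal taxa separated from the rest by 10 fixed differences,
  ## plus unshared noise columns
  set.seed(5)
  samples <- c(paste0("F", 1:3), paste0("S", 1:3), "OUT")
  g <- matrix(0L, length(samples), 50, dimnames = list(samples, NULL))
  g[paste0("F", 1:3), 1:10] <- 1L            # fixed clade signal
  g["OUT", 11:30] <- 3L
  g["S1", 31:35] <- 2L; g["S2", 36:40] <- 2L
  bs <- bootstrapSupport(g, focal = paste0("F", 1:3), outgroup = "OUT",
                         reps = 100, seed = 1)
  expect_identical(bs$category, paste0("F", 1:3))
  expect_gte(bs$support, 0.99)

  ## reps = 1 with a fixed seed is reproducible and in {0,1}
  b1 <- bootstrapSupport(g, paste0("F", 1:3), "OUT", reps = 1, seed = 42)
  b2 <- bootstrapSupport(g, paste0("F", 1:3), "OUT", reps = 1, seed = 42)
  expect_identical(b1$support, b2$support)
  expect_true(b1$support %in% c(0, 1))

  ## identical sequences: degenerate window, no category
  g0 <- matrix(1L, length(samples), 20, dimnames = list(samples, NULL))
  b0 <- bootstrapSupport(g0, paste0("F", 1:3), "OUT", reps = 5, seed = 1)
  expect_identical(b0$category, character(0))
  expect_true(is.na(b0$support))
})
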