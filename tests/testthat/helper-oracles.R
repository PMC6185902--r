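## Shared fixtures and independent oracles for the test suite.
## Oracle code here deliberately avoids the package's own internals.

options(meiodrive.verbose = FALSE)

## ---- tiny variant matrices ----------------------------------------------

## build a VariantMatrix from a character matrix of bases ("A".."T", "." = NA)
vmFromBases <- function(bases, pos, chrom = "chr1") {
  codes <- matrix(match(bases, c("A", "C", "G", "T")) - 1L,
                  nrow = nrow(bases))
  codes[bases == "."] <- -1L
  VariantMatrix(rownames(bases), setNames(list(as.integer(pos)), chrom),
                setNames(list(codes), chrom))
}

## ---- phylogenetics oracles ----------------------------------------------

## brute-force pairwise difference counter, independent of pDistance()
bruteDistance <- function(geno) {
  n <- nrow(geno)
  d <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(geno[i, ] != geno[j, ]) / ncol(geno)
  d
}

## bipartitions (as canonical strings of tip labels) of an unrooted ape tree,
## one per internal edge; implemented from the edge matrix directly
treeBipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    side <- sort(below(child))
    other <- sort(setdiff(tree$tip.label, side))
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  sort(unique(out))
}

## all rooted clades (tip-label sets) of a rooted ape tree, via edge matrix
bruteClades <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  nodes <- c(seq_len(n_tip), (n_tip + 1L):(n_tip + tree$Nnode))
  lapply(nodes, function(nd) sort(below(nd)))
}

## brute-force reference for classifyGrouping without an anchor
bruteClassify <- function(tree, focal) {
  clades <- bruteClades(tree)
  cand <- Filter(function(s) length(s) > 0 && all(s %in% focal), clades)
  if (!length(cand)) return(character(0))
  sizes <- lengths(cand)
  best <- cand[sizes == max(sizes)]
  keys <- vapply(best, paste, "", collapse = "|")
  best[[which.min(match(keys, sort(keys)))]]
}

## brute-force reference for the anchored variant
bruteClassifyAnchor <- function(tree, focal, anchor) {
  clades <- bruteClades(tree)
  ok <- Filter(function(s) anchor %in% s && length(s) >= 2 &&
                 all(s %in% c(focal, anchor)), clades)
  if (!length(ok)) return(character(0))
  sizes <- lengths(ok)
  sort(setdiff(ok[[which.min(sizes)]], anchor))
}

## exhaustive least-squares topology search (small n), using phangorn's
## topology enumeration but fitting branch lengths by plain lm algebra
lsBestTopology <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(utils::combn(n, 2))
  dvec <- d[pairs]
  best <- NULL
  for (ti in seq_along(tops)) {
    tp <- tops[[ti]]   # [[ ]] reattaches tip labels on a multiPhylo
    n_edge <- nrow(tp$edge)
    ## incidence: edge e separates pair (i,j) iff exactly one of them is
    ## below the child of e
    n_tip <- length(tp$tip.label)
    kids <- split(tp$edge[, 2], tp$edge[, 1])
    below <- function(node) {
      if (node <= n_tip) return(node)
      unlist(lapply(kids[[as.character(node)]], below))
    }
    A <- matrix(0, nrow(pairs), n_edge)
    for (e in seq_len(n_edge)) {
      side <- below(tp$edge[e, 2])
      i_in <- match(labs[pairs[, 1]], tp$tip.label) %in% side
      j_in <- match(labs[pairs[, 2]], tp$tip.label) %in% side
      A[, e] <- as.numeric(xor(i_in, j_in))
    }
    ls <- stats::lm.fit(A, dvec)
    fit <- ifelse(is.na(ls$coefficients), 0, ls$coefficients)
    resid <- sum(ls$residuals^2)
    if (is.null(best) || resid < best$resid) {
      tq <- tp; tq$edge.length <- as.numeric(fit)
      best <- list(tree = tq, resid = resid)
    }
  }
  best
}

## random additive distance matrix from a random tree; returns both
randomAdditive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 0.5))
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}

## ---- binomial oracle ------------------------------------------------------

## exact upper-tail binomial P(X >= k) by direct pmf summation
bruteBinomUpper <- function(k, n, p) {
  j <- seq.int(max(0, k), n)
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

## ---- codon alignment shortcuts -------------------------------------------

alnFromStrings <- function(ingroup, outgroup = character(0), id = "g1") {
  CodonAlignment(id, Biostrings::DNAStringSet(ingroup),
                 Biostrings::DNAStringSet(outgroup))
}

## lean simulation parameters for scan-level tests: one region-sized
## chromosome, ~5000 variable sites across 13 haploid samples
leanScanParams <- function(seed, tracts = list(), killerSplit = 0.02) {
  simulationParams(seed = seed, chromosomes = c(chrR = 50000L),
                   regionChrom = "chrR", regionStart = 1L, regionEnd = 50000L,
                   nSensitive = 6L, nKillerA = 4L, nKillerB = 0L,
                   nOutgroup = 3L, thetaWithin = 0.0023,
                   killerSplit = killerSplit, outgroupDepth = 0.05,
                   nRegionGenes = 0L, nBackgroundGenes = 0L,
                   nRepeatClusters = 0L, tracts = tracts)
}
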