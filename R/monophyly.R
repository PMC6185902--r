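#' Root a tree on a designated outgroup
#'
#' If the outgroup forms a clade on the unrooted tree, the root is placed at
#' the midpoint of its stem edge.  Otherwise the tree is rooted on the
#' terminal edge of the first outgroup id (deterministic fallback, with a
#' warning).
#'
#' @param tree An unrooted `ape::phylo`.
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted `ape::phylo`.
#' @export
rootOnOutgroup <- function(tree, outgroup) {
  missing_ids <- setdiff(outgroup, tree$tip.label)
  if (length(missing_ids))
    stop("outgroup id(s) not in tree: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    warning("outgroup not monophyletic; rooting on terminal edge of '",
            outgroup[1], "'", call. = FALSE)
    rooted <- ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
  }
  .midpointRootEdge(rooted)
}

## split the total stem length evenly between the two root children
.midpointRootEdge <- function(tree) {
  root <- length(tree$tip.label) + 1L
  idx <- which(tree$edge[, 1] == root)
  if (length(idx) == 2L && !is.null(tree$edge.length)) {
    total <- sum(tree$edge.length[idx])
    tree$edge.length[idx] <- total / 2
  }
  tree
}

## descendant tip-label sets for every node of a rooted tree (tips included)
.cladeTipSets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Classify which focal samples form a monophyletic group
#'
#' Without an anchor, returns the leaf set of the largest clade whose leaves
#' are a non-empty subset of the focal set (ties broken by the
#' lexicographically smallest sorted id tuple).  With an anchor, returns the
#' focal members of the smallest clade that contains the anchor and whose
#' leaves all lie in the focal set plus the anchor; empty when no clade
#' beyond the anchor leaf itself qualifies.
#'
#' @param tree A rooted `ape::phylo`.
#' @param focal Character vector of focal tip labels.
#' @param anchor Optional single tip label, not in `focal`.
#' @return Sorted character vector of focal ids (possibly empty).
#' @export
classifyGrouping <- function(tree, focal, anchor = NULL) {
  if (!ape::is.rooted(tree))
    stop("classifyGrouping requires a rooted tree", call. = FALSE)
  if (!all(focal %in% tree$tip.label))
    stop("focal id(s) not in tree", call. = FALSE)
  sets <- .cladeTipSets(tree)
  if (is.null(anchor)) {
    best <- character(0); best_key <- ""
    for (s in sets) {
      if (length(s) && all(s %in% focal)) {
        if (length(s) > length(best)) {
          best <- s; best_key <- paste(sort(s), collapse = "|")
        } else if (length(s) == length(best)) {
          key <- paste(sort(s), collapse = "|")
          if (key < best_key) { best <- s; best_key <- key }
        }
      }
    }
    return(sort(best))
  }
  if (length(anchor) != 1L || !(anchor %in% tree$tip.label) || anchor %in% focal)
    stop("anchor must be a single tip label outside the focal set", call. = FALSE)
  admissible <- c(focal, anchor)
  node <- match(anchor, tree$tip.label)
  parent <- integer(length(sets))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  repeat {
    node <- parent[node]
    if (node == 0L) break
    s <- sets[[node]]
    if (!all(s %in% admissible)) break  # supersets can only get worse
    if (length(s) >= 2L) return(sort(setdiff(s, anchor)))
  }
  character(0)
}

#' Bootstrap support for a window's monophyletic grouping
#'
#' Resamples the window's sites with replacement, rebuilds the BioNJ tree
#' each time, and reports the fraction of replicates in which the
#' classification equals the category identified on the original window
#' (support is for the originally identified group, not the best group per
#' replicate).
#'
#' @param geno Samples x sites genotype matrix for the window.
#' @param focal,outgroup,anchor See [classifyGrouping()].
#' @param reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling stream.
#' @return A list with `category` (sorted ids), `support` (fraction in
#'   \[0,1\], NA when the category is empty) and `reps`.
#' @export
bootstrapSupport <- function(geno, focal, outgroup, reps = 100L, seed = 1L,
                             anchor = NULL) {
  stopifnot(reps >= 1L)
  category <- .windowCategory(geno, focal, outgroup, anchor)
  if (length(category) == 0L)
    return(list(category = character(0), support = NA_real_, reps = reps))
  hits <- .withSeed(seed, {
    S <- ncol(geno)
    vapply(seq_len(reps), function(b) {
      cols <- sample.int(S, S, replace = TRUE)
      cat_b <- tryCatch(.windowCategory(geno[, cols, drop = FALSE],
                                        focal, outgroup, anchor),
                        error = function(e) character(0))
      identical(cat_b, category)
    }, logical(1))
  })
  list(category = category, support = mean(hits), reps = reps)
}

## distance -> tree -> root -> classification for one window
.windowCategory <- function(geno, focal, outgroup, anchor = NULL) {
  if (all(geno == geno[1L, ][col(geno)])) return(character(0))  # identical rows
  dm <- pDistance(geno)
  tree <- bionjTree(dm)
  rooted <- suppressWarnings(rootOnOutgroup(tree, outgroup))
  classifyGrouping(rooted, focal, anchor)
}
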