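#' Distance tree by variance-weighted neighbor joining (BioNJ)
#'
#' Agglomerative tree construction from a distance matrix with a parallel
#' variance matrix.  At each step the pair (i,j) minimizing
#' Q(i,j) = (r-2) d(i,j) - S_i - S_j is joined (S_i the row sum over active
#' nodes, r the number of active nodes); branch lengths follow the standard
#' neighbor-joining estimates, and the reduction of distances and variances
#' uses the variance-optimal mixing weight
#' lambda = 1/2 + sum_k (v(j,k) - v(i,k)) / (2 (r-2) v(i,j)), clamped to
#' \[0,1\] (lambda = 1/2 when v(i,j) = 0 or r = 3).  With an uninformative
#' (all-zero) variance matrix, lambda is 1/2 at every step and the procedure
#' reduces exactly to classic neighbor joining; note that a constant positive
#' variance matrix does not, because reduced variances shrink relative to the
#' originals (lambda is scale-invariant in v).  Ties in the pair
#' choice are broken by the smallest (i,j) index pair.  Negative branch
#' length estimates are clamped to zero in the reported tree (count noted);
#' the raw estimates still drive the distance reduction, as in standard
#' neighbor joining.
#'
#' @param d Symmetric distance matrix with row/column names, or the list
#'   returned by [pDistance()].
#' @param v Variance matrix of the same shape (defaults to `d`).
#' @return An unrooted `ape::phylo` tree (basal trifurcation).
#' @export
bionjTree <- function(d, v = NULL) {
  if (is.list(d) && !is.null(d$d)) {
    if (is.null(v)) v <- d$v
    d <- d$d
  }
  if (is.null(v)) v <- d
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have row names", call. = FALSE)
  if (n < 3L) stop("at least 3 taxa required", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)

  D <- unname(d); V <- unname(v)
  sub <- labels          # newick substring per active node
  n_clamped <- 0L
  fmt <- function(x) sprintf("%.17g", x)

  r <- n
  while (r > 3L) {
    S <- rowSums(D)
    Q <- (r - 2) * D - outer(S, S, "+")
    ## smallest Q; ties broken by smallest (i,j), i < j
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (i in seq_len(r - 1L)) {
      qi <- Q[i, (i + 1L):r]
      m <- min(qi)
      if (m < qmin) {
        qmin <- m
        best <- c(i, i + which.min(qi))
      }
    }
    i <- best[1]; j <- best[2]
    dij <- D[i, j]
    bi <- dij / 2 + (S[i] - S[j]) / (2 * (r - 2))
    bj <- dij - bi
    ## raw estimates drive the reduction; clamping applies to output only
    bi_out <- bi; bj_out <- bj
    if (bi_out < 0) { bi_out <- 0; n_clamped <- n_clamped + 1L }
    if (bj_out < 0) { bj_out <- 0; n_clamped <- n_clamped + 1L }

    vij <- V[i, j]
    if (vij <= 0) {
      lambda <- 0.5
    } else {
      k <- setdiff(seq_len(r), c(i, j))
      lambda <- 0.5 + sum(V[j, k] - V[i, k]) / (2 * (r - 2) * vij)
      lambda <- min(1, max(0, lambda))
    }

    k <- setdiff(seq_len(r), c(i, j))
    newD <- lambda * (D[i, k] - bi) + (1 - lambda) * (D[j, k] - bj)
    newV <- lambda * V[i, k] + (1 - lambda) * V[j, k] - lambda * (1 - lambda) * vij
    newSub <- paste0("(", sub[i], ":", fmt(bi_out), ",", sub[j], ":", fmt(bj_out), ")")

    keep <- k
    D <- D[keep, keep, drop = FALSE]; V <- V[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newD), c(newD, 0))
    V <- rbind(cbind(V, newV), c(newV, 0))
    sub <- c(sub[keep], newSub)
    r <- r - 1L
  }

  ## final three-way join
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(b1, b2, b3)
  n_clamped <- n_clamped + sum(bl < 0)
  bl[bl < 0] <- 0
  if (n_clamped > 0)
    .log("bionjTree: ", n_clamped, " negative branch length(s) clamped to 0")
  newick <- paste0("(", sub[1], ":", fmt(bl[1]), ",", sub[2], ":", fmt(bl[2]),
                   ",", sub[3], ":", fmt(bl[3]), ");")
  ape::read.tree(text = newick)
}
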