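#' Pairwise p-distance matrix for a window of SNP genotypes
#'
#' d(i,j) is the proportion of sites at which samples i and j carry different
#' alleles.  The accompanying variance matrix, used by the BioNJ weighting,
#' is initialized to the distance itself.
#'
#' A Jukes-Cantor multiple-hit correction is available but off by default:
#' windows are short (50 variable sites), and the correction is undefined
#' when a pairwise p-distance reaches the saturation bound of 3/4 (such
#' entries are capped just below saturation, with a warning).
#'
#' @param geno Integer samples x sites genotype matrix (no missing calls;
#'   rows named by sample).
#' @param correction `"none"` (default) or `"JC69"` for the Jukes-Cantor
#'   transform d = -3/4 log(1 - 4p/3).
#' @return A list with elements `labels`, `d` (distance matrix) and `v`
#'   (variance matrix, initialized to `d`).
#' @export
pDistance <- function(geno, correction = c("none", "JC69")) {
  correction <- match.arg(correction)
  if (is.null(rownames(geno))) stop("genotype matrix must have row names", call. = FALSE)
  n <- nrow(geno); S <- ncol(geno)
  if (n < 3L) stop("at least 3 samples required for tree building", call. = FALSE)
  if (S < 1L) stop("window must contain at least one site", call. = FALSE)
  if (any(geno == MISSING_CODE))
    stop("missing calls present; apply filterVariants() first", call. = FALSE)
  matches <- matrix(0, n, n)
  for (b in 0:3) {
    Xb <- geno == b
    if (any(Xb)) matches <- matches + tcrossprod(Xb)
  }
  d <- (S - matches) / S
  diag(d) <- 0
  if (correction == "JC69") {
    sat <- d >= 0.75
    if (any(sat)) {
      warning("p-distance at or beyond the JC69 saturation bound; capped",
              call. = FALSE)
      d[sat] <- 0.75 - 1e-9
    }
    d <- -0.75 * log(1 - 4 * d / 3)
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(geno), rownames(geno))
  list(labels = rownames(geno), d = d, v = d)
}
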