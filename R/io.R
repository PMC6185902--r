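#' Read a genome FASTA
#'
#' Reads a (multi-)FASTA into a [Biostrings::DNAStringSet].  Sequences are
#' uppercased and any IUPAC ambiguity letter other than A/C/G/T/N is mapped
#' to N, with the number of substitutions reported.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA (", conditionMessage(e),
                                            "): ", path, call. = FALSE))
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  ## keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome identifiers in ", path, call. = FALSE)
  amb <- sum(Biostrings::letterFrequency(seqs, "MRWSYKVHDB"))
  if (amb > 0) {
    seqs <- Biostrings::DNAStringSet(Biostrings::replaceAmbiguities(seqs, new = "N"))
    .log(amb, " non-ACGTN base(s) replaced with N in ", basename(path))
  }
  seqs
}

#' Write a genome FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @param width Line width.
#' @export
writeGenome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

.baseCode <- function(b) {
  code <- match(b, BASES) - 1L
  code
}

#' Read haploid SNP genotypes from a VCF
#'
#' Retains biallelic SNP records only; multi-allelic records and indels are
#' dropped with counts reported.  Haploid genotypes `0`/`1` map to the REF /
#' ALT base code (A=0, C=1, G=2, T=3); `.` maps to the missing code (-1).
#' A diploid-style genotype (containing `/` or `|`) is a configuration error
#' and names the offending sample.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A [VariantMatrix-class].
#' @export
readVariants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)

  ploidy_bad <- matrix(grepl("[/|]", gt), nrow = nrow(gt))
  if (any(ploidy_bad)) {
    bad_sample <- samples[which(ploidy_bad, arr.ind = TRUE)[1, 2]]
    stop("diploid-style genotype encountered for sample '", bad_sample,
         "'; haploid calls required", call. = FALSE)
  }

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & ref %in% BASES &
    !is.na(alt) & nchar(alt) == 1L & alt %in% BASES
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    .log(n_drop, " non-biallelic-SNP record(s) dropped (indels/multi-allelic)")

  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, , drop = FALSE]
  chroms <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  refc <- .baseCode(fix[, "REF"]); altc <- .baseCode(fix[, "ALT"])

  pos_l <- list(); geno_l <- list()
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    sel <- sel[order(pos[sel])]
    g <- gt[sel, , drop = FALSE]
    codes <- matrix(MISSING_CODE, nrow = length(samples), ncol = length(sel))
    for (j in seq_along(sel)) {
      gj <- g[j, ]
      cj <- rep(MISSING_CODE, length(samples))
      cj[!is.na(gj) & gj == "0"] <- refc[sel[j]]
      cj[!is.na(gj) & gj == "1"] <- altc[sel[j]]
      codes[, j] <- cj
    }
    pos_l[[chrom]] <- pos[sel]
    geno_l[[chrom]] <- codes
  }
  VariantMatrix(samples, pos_l, geno_l)
}

#' Write a VariantMatrix as a haploid VCF
#'
#' The inverse of [readVariants()] up to REF/ALT labelling: reading the file
#' back yields an identical matrix.
#'
#' @param vm A [VariantMatrix-class].
#' @param path Output path.
#' @param refGenome Optional `DNAStringSet`; when given, REF is taken from the
#'   reference base at each position (falling back to the first observed
#'   allele when the reference base is not among the observed alleles).
#' @export
writeVariants <- function(vm, path, refGenome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=meiodrive",
               paste0(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sampleNames(vm)), collapse = "\t")), con)
  for (chrom in chromNames(vm)) {
    p <- positions(vm, chrom); g <- genotypes(vm, chrom)
    if (!length(p)) next
    m <- ncol(g)
    gm <- g; gm[gm == MISSING_CODE] <- NA_integer_
    n_alleles <- apply(gm, 2, function(x) length(unique(x[!is.na(x)])))
    if (any(n_alleles > 2L))
      stop("site ", chrom, ":", p[which(n_alleles > 2L)[1]],
           " has more than two alleles", call. = FALSE)
    lo <- suppressWarnings(apply(gm, 2, min, na.rm = TRUE))
    hi <- suppressWarnings(apply(gm, 2, max, na.rm = TRUE))
    lo[!is.finite(lo)] <- 0L; hi[!is.finite(hi)] <- 0L
    refc <- lo
    if (!is.null(refGenome) && chrom %in% names(refGenome)) {
      chars <- strsplit(as.character(refGenome[[chrom]]), "")[[1]]
      rb <- match(chars[p], BASES) - 1L
      use <- !is.na(rb) & (rb == lo | rb == hi)
      refc[use] <- rb[use]
    }
    altc <- ifelse(refc == lo, hi, lo)
    mono <- altc == refc
    altc[mono] <- vapply(refc[mono], function(r) setdiff(0:3, r)[1], 0L)
    gt <- matrix(".", nrow(g), m)
    gt[!is.na(gm)] <- ifelse(gm[!is.na(gm)] ==
                               refc[col(gm)][!is.na(gm)], "0", "1")
    gt_str <- do.call(paste, c(as.data.frame(t(gt), stringsAsFactors = FALSE),
                               sep = "\t"))
    writeLines(paste(chrom, p, ".", BASES[refc + 1L], BASES[altc + 1L],
                     ".", "PASS", ".", "GT", gt_str, sep = "\t"), con)
  }
  invisible(path)
}

#' Read RepeatMasker annotations
#'
#' Parses the standard 15-column RepeatMasker `.out` format (three header
#' lines, whitespace-separated) or, as a fallback, a 6-column BED file whose
#' name column holds `family` or `family#class`.  Coordinates are returned as
#' a [GenomicRanges::GRanges] with metadata columns `family` and `class`.
#'
#' @param path Path to a RepeatMasker `.out` or BED file.
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   validate coordinates (errors report the offending line).
#' @return A `GRanges` with mcols `family`, `class`.
#' @export
readRepeatMasker <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("repeat annotation file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*SW\\s", first) || grepl("score", first)) {
    lines <- readLines(path)
    body <- lines[-(1:3)]
    body <- body[nzchar(trimws(body))]
    if (!length(body))
      return(GenomicRanges::GRanges(family = character(), class = character()))
    fields <- strsplit(trimws(body), "\\s+")
    n_ok <- vapply(fields, length, 1L) >= 11L
    if (any(!n_ok))
      stop("malformed RepeatMasker .out line ", which(!n_ok)[1] + 3L, call. = FALSE)
    chrom <- vapply(fields, `[[`, "", 5L)
    start <- as.integer(vapply(fields, `[[`, "", 6L))
    end <- as.integer(vapply(fields, `[[`, "", 7L))
    family <- vapply(fields, `[[`, "", 10L)
    class <- vapply(fields, `[[`, "", 11L)
  } else {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "")
    if (ncol(bed) < 4L) stop("BED repeat file needs at least 4 columns", call. = FALSE)
    chrom <- bed[[1]]
    start <- bed[[2]] + 1L  # BED is 0-based half-open
    end <- bed[[3]]
    fam_cls <- strsplit(bed[[4]], "#", fixed = TRUE)
    family <- vapply(fam_cls, `[[`, "", 1L)
    class <- vapply(fam_cls, function(x) if (length(x) > 1) x[2] else "Unknown", "")
  }
  if (any(!nzchar(family))) stop("empty repeat family name", call. = FALSE)
  if (!is.null(seqlengths)) {
    bad <- which(!(chrom %in% names(seqlengths)) | end > seqlengths[chrom] | start < 1L)
    if (length(bad))
      stop("repeat coordinate outside chromosome at line ", bad[1],
           " (", chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]], ")",
           call. = FALSE)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         family = family, class = class)
}

#' Read per-cytosine methylation calls
#'
#' Two bedGraph dialects are supported: the 4-column dialect
#' (chrom, start, end, methylation percentage) and the 6-column coverage
#' dialect (chrom, start, end, percentage, methylated count, unmethylated
#' count).  Intervals use 0-based half-open coordinates and are expanded to
#' 1-based per-position records.
#'
#' @param path Path to a bedGraph-like file.
#' @param seqlengths Optional named chromosome lengths for validation.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `frac`
#'   (methylated fraction in \[0,1\]), `meth` and `total` read counts
#'   (NA for the 4-column dialect).
#' @export
readMethylation <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("methylation file not found: ", path, call. = FALSE)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!ncol(tab) %in% c(4L, 6L))
    stop("methylation bedGraph must have 4 or 6 columns, found ", ncol(tab),
         call. = FALSE)
  if (!is.null(seqlengths)) {
    bad <- which(!(tab[[1]] %in% names(seqlengths)) |
                   tab[[3]] > seqlengths[tab[[1]]] | tab[[2]] < 0L)
    if (length(bad))
      stop("methylation coordinate outside chromosome at line ", bad[1], call. = FALSE)
  }
  widths <- tab[[3]] - tab[[2]]
  idx <- rep.int(seq_len(nrow(tab)), widths)
  pos <- sequence(widths) + rep.int(tab[[2]], widths)  # 1-based positions
  if (ncol(tab) == 6L) {
    meth <- tab[[5]][idx]; unmeth <- tab[[6]][idx]
    total <- meth + unmeth
    if (any(meth < 0 | unmeth < 0)) stop("negative methylation counts", call. = FALSE)
    frac <- ifelse(total > 0, meth / total, NA_real_)
  } else {
    meth <- rep(NA_real_, length(idx)); total <- rep(NA_real_, length(idx))
    frac <- tab[[4]][idx] / 100
  }
  data.frame(chrom = tab[[1]][idx], pos = as.integer(pos),
             frac = frac, meth = meth, total = total,
             stringsAsFactors = FALSE)
}

#' Read a coverage track (bedGraph)
#'
#' @param path Path to a 4-column bedGraph of read depth.
#' @param seqlengths Optional named chromosome lengths (attached to the result
#'   and used for validation).
#' @return A `GRanges` with a `score` column (depth over each interval).
#' @export
readCoverage <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("negative coverage values", call. = FALSE)
  if (!is.null(seqlengths)) {
    bad <- which(!(as.character(GenomicRanges::seqnames(gr)) %in% names(seqlengths)) |
                   GenomicRanges::end(gr) > seqlengths[as.character(GenomicRanges::seqnames(gr))])
    if (length(bad))
      stop("coverage coordinate outside chromosome at line ", bad[1], call. = FALSE)
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Read gene models from a GFF3
#'
#' Builds one gene model per gene: ordered CDS intervals (5' to 3'), strand,
#' and the spliced CDS length.  Genes whose spliced length is not a multiple
#' of three are flagged invalid rather than dropped.
#'
#' @param path Path to a GFF3 file.
#' @param seqlengths Optional named chromosome lengths for validation.
#' @return A list of gene models; each element is a list with fields
#'   `geneID`, `chrom`, `strand`, `cds` (a `GRanges`, genomic order),
#'   `splicedLength`, `valid`.
#' @export
readGeneModels <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", path, call. = FALSE)
  gene_of <- .cdsGeneID(cds)
  if (!is.null(seqlengths)) {
    bad <- which(GenomicRanges::end(cds) >
                   seqlengths[as.character(GenomicRanges::seqnames(cds))])
    if (length(bad))
      stop("CDS coordinate outside chromosome for gene ", gene_of[bad[1]],
           call. = FALSE)
  }
  models <- list()
  for (gid in unique(gene_of)) {
    g <- cds[gene_of == gid]
    g <- GenomicRanges::sort(g)  # genomic order; reverse strand handled at extraction
    strand <- as.character(GenomicRanges::strand(g))[1]
    ov <- GenomicRanges::findOverlaps(g, drop.self = TRUE)
    valid <- length(ov) == 0L
    sl <- sum(GenomicRanges::width(g))
    if (sl %% 3L != 0L) valid <- FALSE
    models[[gid]] <- list(geneID = gid,
                          chrom = as.character(GenomicRanges::seqnames(g))[1],
                          strand = strand, cds = g,
                          splicedLength = sl, valid = valid)
  }
  n_bad <- sum(!vapply(models, `[[`, TRUE, "valid"))
  if (n_bad > 0) .log(n_bad, " gene model(s) flagged invalid")
  models
}

.cdsGeneID <- function(cds) {
  id <- cds$Parent
  if (!is.null(id)) {
    id <- vapply(id, function(x) if (length(x)) x[[1]] else NA_character_, "")
    id <- sub("^(mRNA|transcript)[:.]", "", id)
    id <- sub("\\.t\\d+$", "", id)
    id <- sub("-T\\d+$", "", id)
  }
  if (is.null(id) || all(is.na(id))) id <- cds$ID
  if (is.null(id) || all(is.na(id)))
    stop("CDS features carry neither Parent nor ID attributes", call. = FALSE)
  as.character(id)
}
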