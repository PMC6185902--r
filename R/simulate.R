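#' Parameters for the synthetic drive-haplotype dataset
#'
#' Defaults describe a desk-scale multi-strain haploid species with a
#' diverged non-recombining region: a star-like sensitive genealogy, a
#' killer clade separated at a configurable depth, an outgroup species,
#' low-GC repeat clusters carrying high methylation and elevated ChIP
#' coverage, and genes evolving with per-gene selection intensity omega.
#' Rates are expected substitutions per site on the respective branch.
#'
#' @param seed Integer master seed.
#' @param chromosomes Named vector of chromosome lengths (bp).
#' @param regionChrom,regionStart,regionEnd Drive-region bounds (1-based,
#'   inclusive) on one chromosome.
#' @param nSensitive,nKillerA,nKillerB,nOutgroup Sample design.
#' @param thetaWithin Private-branch depth per sample (pairwise distance
#'   between two sensitives is ~2x this).
#' @param killerSplit Depth of the killer-clade stem across the region.
#' @param outgroupDepth Depth of the outgroup stem, genome-wide.
#' @param tracts List of planted recombination tracts, each
#'   `list(sample=, start=, end=)` (the killer sample's region haplotype is
#'   replaced by the sensitive consensus over the tract).
#' @param nRegionGenes,nBackgroundGenes Gene counts inside/outside the region.
#' @param geneLengths Candidate spliced CDS lengths (bp, multiples of 3).
#' @param omega Per-gene dN/dS intensity (scalar recycled, or one per gene;
#'   0 plants purely synonymous coding variation).
#' @param nRepeatClusters,repeatLengths Repeat-cluster count and length range.
#' @param repeatGC GC fraction inside repeat clusters (background is 0.5).
#' @param methRepeat,methBackground Methylated-read fraction at cytosines
#'   inside/outside repeats.
#' @param chipFoldRepeat IP/input fold inside repeats (1 outside).
#' @param missingRate Fraction of genotype cells set to missing.
#' @param strict Error when a tract falls outside the region.
#' @return A named list of validated parameters.
#' @export
simulationParams <- function(seed = 1L,
                             chromosomes = c(chr1 = 100000L, chr3 = 300000L),
                             regionChrom = "chr3",
                             regionStart = 100001L, regionEnd = 260000L,
                             nSensitive = 8L, nKillerA = 4L, nKillerB = 1L,
                             nOutgroup = 5L,
                             thetaWithin = 0.004, killerSplit = 0.02,
                             outgroupDepth = 0.05,
                             tracts = list(),
                             nRegionGenes = 10L, nBackgroundGenes = 20L,
                             geneLengths = seq(300L, 1200L, by = 3L),
                             omega = 0.2,
                             nRepeatClusters = 8L,
                             repeatLengths = c(3000L, 8000L),
                             repeatGC = 0.30,
                             methRepeat = 0.9, methBackground = 0.02,
                             chipFoldRepeat = 3,
                             missingRate = 0, strict = TRUE) {
  stopifnot(thetaWithin >= 0, killerSplit >= 0, outgroupDepth >= 0,
            repeatGC > 0, repeatGC < 1,
            regionChrom %in% names(chromosomes),
            regionStart >= 1, regionEnd <= chromosomes[[regionChrom]],
            regionStart < regionEnd,
            all(geneLengths %% 3L == 0L))
  for (tr in tracts) {
    if (tr$start < regionStart || tr$end > regionEnd) {
      if (strict) stop("tract outside region: ", tr$sample, call. = FALSE)
      warning("tract outside region: ", tr$sample, call. = FALSE)
    }
  }
  as.list(environment())
}

## sample names by role
.simSamples <- function(p) {
  list(sensitive = paste0("sens", seq_len(p$nSensitive)),
       focal = paste0("kA", seq_len(p$nKillerA)),
       anchor = if (p$nKillerB > 0) paste0("kB", seq_len(p$nKillerB)) else character(0),
       outgroup = paste0("out", seq_len(p$nOutgroup)))
}

#' Simulate a complete toy drive-haplotype dataset
#'
#' Generates the reference genome, haploid variant matrix, gene models,
#' repeat annotations, methylation and ChIP/input coverage tracks, and a
#' ground-truth record sufficient to score every analysis stage.  With
#' `dir` given, everything is also written in standard formats (FASTA, VCF,
#' GFF3, RepeatMasker .out, bedGraph, truth JSON); outputs are byte-stable
#' for a fixed seed.
#'
#' @param params From [simulationParams()].
#' @param dir Output directory, or NULL to return in-memory objects only.
#' @return A list: `genome`, `vm` ([VariantMatrix-class]), `models`,
#'   `repeats` (`GRanges`), `methylation`, `ipCoverage`, `inputCoverage`,
#'   `samples` (role list), `truth`, and `files` (paths, when written).
#' @export
simulateDriveData <- function(params = simulationParams(), dir = NULL) {
  p <- params
  roles <- .simSamples(p)
  samples <- unlist(roles, use.names = FALSE)
  .withSeed(p$seed, {
    genome_parts <- .simGenomeAndRepeats(p)
    genome_chars <- genome_parts$chars
    repeats <- genome_parts$repeats
    models <- .simGenes(p, genome_chars, repeats)
    ## write gene reference ORFs into the genome
    for (m in models$writes)
      genome_chars[[m$chrom]][m$at] <- m$bases
    genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                              "", collapse = ""))
    vars <- .simMutations(p, genome_chars, models$models, roles)
    vars <- .applyTracts(vars, p, roles)
    vm <- .variantsToMatrix(vars, samples, genome_chars, p)
    tracks <- .simChromatin(p, genome_chars, repeats)
    truth <- .simTruth(p, roles, vars, models$models, repeats)
    out <- list(genome = genome, vm = vm, models = models$models,
                repeats = repeats, methylation = tracks$meth,
                ipCoverage = tracks$ip, inputCoverage = tracks$input,
                samples = roles, truth = truth)
    if (!is.null(dir)) out$files <- .writeSimFiles(out, p, dir)
    out
  })
}

## reference genome with low-GC repeat clusters; returns per-chrom char
## vectors plus the repeat GRanges
.simGenomeAndRepeats <- function(p) {
  chars <- lapply(p$chromosomes, function(L)
    sample(BASES, L, replace = TRUE, prob = c(0.25, 0.25, 0.25, 0.25)))
  names(chars) <- names(p$chromosomes)
  fams <- c("Tad1", "Punt", "Sly1", "Guest", "Dab2")
  reps <- list(); ri <- 0L
  gc <- p$repeatGC
  prob_rep <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ## most clusters inside the region (bordering the inversions), some outside
  n_in <- ceiling(p$nRepeatClusters * 0.75)
  for (i in seq_len(p$nRepeatClusters)) {
    len <- sample(seq(p$repeatLengths[1], p$repeatLengths[2], by = 100L), 1L)
    if (i <= n_in) {
      chrom <- p$regionChrom
      start <- sample(seq(p$regionStart, p$regionEnd - len, by = 50L), 1L)
    } else {
      chrom <- names(p$chromosomes)[1]
      start <- sample(seq(1L, p$chromosomes[[1]] - len, by = 50L), 1L)
    }
    chars[[chrom]][start:(start + len - 1L)] <-
      sample(BASES, len, replace = TRUE, prob = prob_rep)
    ri <- ri + 1L
    reps[[ri]] <- data.frame(chrom = chrom, start = start,
                             end = start + len - 1L,
                             family = fams[(i - 1L) %% length(fams) + 1L])
  }
  if (length(reps)) {
    rdf <- do.call(rbind, reps)
    gr <- GenomicRanges::GRanges(rdf$chrom, IRanges::IRanges(rdf$start, rdf$end),
                                 family = rdf$family, class = "DNA_transposon")
  } else {
    gr <- GenomicRanges::GRanges(family = character(), class = character())
  }
  list(chars = chars, repeats = GenomicRanges::sort(gr))
}

## place genes outside repeats; reference CDS built from sense codons
## (ATG ... TAA) so every gene is a clean ORF; all exon lengths are
## multiples of 3, so splicing phases are 0
.simGenes <- function(p, chars, repeats) {
  models <- list(); writes <- list()
  occupied <- repeats
  place <- function(chrom, len) {
    L <- p$chromosomes[[chrom]]
    for (try in 1:200) {
      start <- sample.int(L - len - 10L, 1L)
      cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + len - 1L))
      if (!any(suppressWarnings(IRanges::overlapsAny(cand, occupied)))) {
        occupied <<- suppressWarnings(c(occupied, cand))
        return(start)
      }
    }
    NA_integer_
  }
  n_tot <- p$nRegionGenes + p$nBackgroundGenes
  omega <- rep_len(p$omega, n_tot)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA", "ATG", "TGG"))
  gi <- 0L
  for (i in seq_len(n_tot)) {
    len <- sample(p$geneLengths, 1L)
    in_region <- i <= p$nRegionGenes
    chrom <- if (in_region) p$regionChrom else
      names(p$chromosomes)[1 + (i %% 2 == 0)]
    if (in_region) {
      ## constrained placement inside the region
      for (try in 1:200) {
        start <- sample(seq(p$regionStart, p$regionEnd - len - 10L, by = 1L), 1L)
        cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + len - 1L))
        if (!any(suppressWarnings(IRanges::overlapsAny(cand, occupied)))) {
          occupied <- suppressWarnings(c(occupied, cand)); break
        }
        start <- NA_integer_
      }
    } else start <- place(chrom, len)
    if (is.na(start)) next
    gi <- gi + 1L
    gid <- sprintf("gene%03d", gi)
    n_cod <- len %/% 3L
    body <- sample(sense, n_cod - 2L, replace = TRUE)
    orf <- c("ATG", body, "TAA")
    strand <- sample(c("+", "-"), 1L)
    seq_fwd <- paste(orf, collapse = "")
    genomic <- if (strand == "+") seq_fwd else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
    ## one or two exons, each a multiple of 3
    if (n_cod >= 40L && runif(1) < 0.5) {
      cut <- 3L * sample.int(n_cod - 2L, 1L)
      intron <- 60L
      cds <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
        c(start, start + cut + intron),
        c(start + cut - 1L, start + intron + len - 1L)), strand = strand)
    } else {
      cds <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(start, start + len - 1L),
                                    strand = strand)
    }
    ## map the genomic ORF characters to the exon positions
    at <- unlist(mapply(seq, GenomicRanges::start(cds), GenomicRanges::end(cds),
                        SIMPLIFY = FALSE))
    writes[[gid]] <- list(chrom = chrom, at = at,
                          bases = strsplit(genomic, "")[[1]])
    models[[gid]] <- list(geneID = gid, chrom = chrom, strand = strand,
                          cds = cds, splicedLength = len, valid = TRUE,
                          omega = omega[i], inRegion = in_region)
  }
  list(models = models, writes = writes)
}

## Poisson mutations on the fixed genealogy.  Each variant records position,
## derived base, carriers (sample names), branch class, and for CDS hits the
## gene and NG86 class.
.simMutations <- function(p, chars, models, roles) {
  ingroup <- c(roles$sensitive, roles$focal, roles$anchor)
  all_samples <- c(ingroup, roles$outgroup)
  region_chrom <- p$regionChrom
  ## per-gene codon bookkeeping for class-exact placement
  genes <- .geneCodonIndex(models, chars)
  used_codon <- lapply(genes$byGene, function(g) logical(g$nCodon))
  vars <- list(); vi <- 0L
  add <- function(chrom, n, carriers, branch) {
    if (n == 0L) return(invisible(NULL))
    L <- p$chromosomes[[chrom]]
    pos <- sample.int(L, n)
    for (pp in pos) {
      hit <- .geneAt(genes, chrom, pp)
      if (is.null(hit)) {
        ref <- chars[[chrom]][pp]
        derived <- sample(setdiff(BASES, ref), 1L)
        vi <<- vi + 1L
        vars[[vi]] <<- list(chrom = chrom, pos = pp, derived = derived,
                            carriers = carriers, branch = branch,
                            gene = NA_character_, class = NA_character_)
      } else {
        mv <- .placeCodingMutation(hit$gene, genes$byGene[[hit$gene]],
                                   used_codon[[hit$gene]], chars)
        if (is.null(mv)) next
        used_codon[[hit$gene]][mv$codon] <<- TRUE
        vi <<- vi + 1L
        vars[[vi]] <<- list(chrom = chrom, pos = mv$pos, derived = mv$derived,
                            carriers = carriers, branch = branch,
                            gene = hit$gene, class = mv$class)
      }
    }
  }
  for (chrom in names(p$chromosomes)) {
    L <- p$chromosomes[[chrom]]
    for (smp in all_samples)
      add(chrom, rpois(1, p$thetaWithin * L), smp, "private")
    add(chrom, rpois(1, p$outgroupDepth * L), roles$outgroup, "outgroup")
  }
  region_len <- p$regionEnd - p$regionStart + 1L
  n_ka <- rpois(1, p$killerSplit * region_len)
  reg_pos <- function(n) sample(seq(p$regionStart, p$regionEnd), n)
  addRegion <- function(n, carriers, branch) {
    if (n == 0L) return(invisible(NULL))
    for (pp in reg_pos(n)) {
      hit <- .geneAt(genes, region_chrom, pp)
      if (is.null(hit)) {
        ref <- chars[[region_chrom]][pp]
        derived <- sample(setdiff(BASES, ref), 1L)
        vi <<- vi + 1L
        vars[[vi]] <<- list(chrom = region_chrom, pos = pp, derived = derived,
                            carriers = carriers, branch = branch,
                            gene = NA_character_, class = NA_character_)
      } else {
        mv <- .placeCodingMutation(hit$gene, genes$byGene[[hit$gene]],
                                   used_codon[[hit$gene]], chars)
        if (is.null(mv)) next
        used_codon[[hit$gene]][mv$codon] <<- TRUE
        vi <<- vi + 1L
        vars[[vi]] <<- list(chrom = region_chrom, pos = mv$pos,
                            derived = mv$derived, carriers = carriers,
                            branch = branch, gene = hit$gene, class = mv$class)
      }
    }
  }
  addRegion(n_ka, roles$focal, "killerA")
  if (length(roles$anchor))
    addRegion(rpois(1, p$killerSplit * region_len), roles$anchor, "killerB")
  ## drop duplicate positions (later draws lose)
  key <- vapply(vars, function(v) paste0(v$chrom, ":", v$pos), "")
  vars[!duplicated(key)]
}

## index of CDS positions per chromosome -> gene
.geneCodonIndex <- function(models, chars) {
  byGene <- list(); lookup <- list()
  for (m in models) {
    at <- unlist(mapply(seq, GenomicRanges::start(m$cds),
                        GenomicRanges::end(m$cds), SIMPLIFY = FALSE))
    byGene[[m$geneID]] <- list(chrom = m$chrom, at = at, strand = m$strand,
                               omega = m$omega, nCodon = length(at) %/% 3L)
    lookup[[m$chrom]] <- rbind(lookup[[m$chrom]],
                               data.frame(start = min(at), end = max(at),
                                          gene = m$geneID,
                                          stringsAsFactors = FALSE))
  }
  lookup <- lapply(lookup, function(df) df[order(df$start), ])
  list(byGene = byGene, lookup = lookup)
}

.geneAt <- function(genes, chrom, pos) {
  df <- genes$lookup[[chrom]]
  if (is.null(df)) return(NULL)
  hit <- which(df$start <= pos & df$end >= pos)
  if (!length(hit)) return(NULL)
  g <- genes$byGene[[df$gene[hit[1]]]]
  if (!(pos %in% g$at)) return(NULL)  # intron
  list(gene = df$gene[hit[1]])
}

## choose an unused codon of the gene and a single-base change of the
## desired NG86 class (syn with prob S/(S + omega N)); NULL when exhausted
.placeCodingMutation <- function(gid, g, used, chars) {
  .ngTables()
  strand <- g$strand
  spliced <- chars[[g$chrom]][g$at]
  if (strand == "-")
    spliced <- rev(chartr("ACGT", "TGCA", spliced))
  n_cod <- g$nCodon
  gc_map <- .geneticCode()
  free <- which(!used)
  free <- setdiff(free, c(1L, n_cod))  # keep start/stop codons intact
  if (!length(free)) return(NULL)
  for (attempt in seq_len(30L)) {
    ci <- if (length(free) == 1L) free else sample(free, 1L)
    cod <- paste(spliced[(3L * ci - 2L):(3L * ci)], collapse = "")
    if (!cod %in% .ngEnv$sense) next
    changes <- .codonChanges(cod, gc_map)
    if (!nrow(changes)) next
    Ng <- .ngEnv$siteN[cod]; Sg <- .ngEnv$siteS[cod]
    p_syn <- Sg / (Sg + g$omega * Ng)
    want <- if (runif(1) < p_syn) "S" else "N"
    opts <- changes[changes$class == want, , drop = FALSE]
    if (!nrow(opts)) next
    pick <- opts[sample.int(nrow(opts), 1L), ]
    off <- 3L * (ci - 1L) + pick$codonPos  # offset in spliced coordinates
    if (strand == "+") {
      pos <- g$at[off]
      derived <- pick$base
    } else {
      pos <- g$at[length(g$at) - off + 1L]
      derived <- chartr("ACGT", "TGCA", pick$base)
    }
    return(list(pos = pos, derived = derived, codon = ci,
                class = if (want == "S") "syn" else "nonsyn"))
  }
  NULL
}

.codonChanges <- function(cod, gc_map) {
  out <- list()
  aa0 <- gc_map[[cod]]
  for (pp in 1:3) {
    b0 <- substr(cod, pp, pp)
    for (b in setdiff(BASES, b0)) {
      m <- cod; substr(m, pp, pp) <- b
      aa <- gc_map[[m]]
      if (aa == "*") next
      out[[length(out) + 1L]] <- data.frame(codonPos = pp, base = b,
                                            class = if (aa == aa0) "S" else "N",
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(codonPos = integer(), base = character(),
                                      class = character()))
  do.call(rbind, out)
}

## recombination tracts copy the sensitive consensus (= reference) into the
## named killer sample: the sample is removed from carrier sets in the tract
.applyTracts <- function(vars, p, roles) {
  if (!length(p$tracts)) return(vars)
  for (tr in p$tracts) {
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      if (v$chrom == p$regionChrom && v$pos >= tr$start && v$pos <= tr$end &&
          tr$sample %in% v$carriers)
        vars[[i]]$carriers <- setdiff(v$carriers, tr$sample)
    }
  }
  vars
}

.variantsToMatrix <- function(vars, samples, chars, p) {
  carriers_n <- vapply(vars, function(v) length(v$carriers), 0L)
  vars <- vars[carriers_n > 0L & carriers_n < length(samples)]
  pos_l <- list(); geno_l <- list()
  for (chrom in names(p$chromosomes)) {
    vc <- Filter(function(v) v$chrom == chrom, vars)
    if (!length(vc)) {
      pos_l[[chrom]] <- integer(0)
      geno_l[[chrom]] <- matrix(integer(0), nrow = length(samples), ncol = 0)
      next
    }
    o <- order(vapply(vc, `[[`, 0, "pos"))
    vc <- vc[o]
    pos <- vapply(vc, `[[`, 0, "pos")
    ref_code <- match(chars[[chrom]][pos], BASES) - 1L
    der_code <- match(vapply(vc, `[[`, "", "derived"), BASES) - 1L
    geno <- matrix(rep(as.integer(ref_code), each = length(samples)),
                   nrow = length(samples), dimnames = list(samples, NULL))
    carriers <- lapply(vc, `[[`, "carriers")
    ci <- match(unlist(carriers), samples)
    si <- rep.int(seq_along(vc), lengths(carriers))
    geno[cbind(ci, si)] <- der_code[si]
    if (p$missingRate > 0) {
      n_cell <- length(geno)
      miss <- which(runif(n_cell) < p$missingRate)
      geno[miss] <- MISSING_CODE
    }
    pos_l[[chrom]] <- as.integer(pos)
    geno_l[[chrom]] <- geno
  }
  VariantMatrix(samples, pos_l, geno_l)
}

## methylation (per-cytosine counts) and ChIP/input coverage (100 bp bins)
.simChromatin <- function(p, chars, repeats) {
  meth <- list(); ip <- list(); input <- list()
  for (chrom in names(p$chromosomes)) {
    L <- p$chromosomes[[chrom]]
    rep_mask <- rep(FALSE, L)
    rr <- repeats[GenomicRanges::seqnames(repeats) == chrom]
    for (k in seq_along(rr))
      rep_mask[GenomicRanges::start(rr)[k]:GenomicRanges::end(rr)[k]] <- TRUE
    c_pos <- which(chars[[chrom]] == "C")
    keep <- rep_mask[c_pos] | (seq_along(c_pos) %% 25L == 0L)
    c_pos <- c_pos[keep]
    cov <- rpois(length(c_pos), 20) + 1L
    level <- ifelse(rep_mask[c_pos], p$methRepeat, p$methBackground)
    mcount <- rbinom(length(c_pos), cov, level)
    meth[[chrom]] <- data.frame(chrom = chrom, pos = c_pos,
                                frac = mcount / cov,
                                meth = mcount, total = cov,
                                stringsAsFactors = FALSE)
    starts <- seq(1L, L - 99L, by = 100L)
    bin_rep <- rep_mask[starts + 49L]
    base_in <- rpois(length(starts), 20)
    fold <- ifelse(bin_rep, p$chipFoldRepeat, 1)
    base_ip <- rpois(length(starts), 20 * fold)
    input[[chrom]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(starts, starts + 99L), score = base_in)
    ip[[chrom]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(starts, starts + 99L), score = base_ip)
  }
  list(meth = do.call(rbind, meth),
       ip = suppressWarnings(do.call(c, unname(ip))),
       input = suppressWarnings(do.call(c, unname(input))))
}

.simTruth <- function(p, roles, vars, models, repeats) {
  ingroup <- c(roles$sensitive, roles$focal, roles$anchor)
  gene_rows <- lapply(models, function(m) {
    gv <- Filter(function(v) identical(v$gene, m$geneID), vars)
    count <- function(branches, cls) sum(vapply(gv, function(v) {
      carriers_ok <- if (identical(branches, "outgroup"))
        setequal(v$carriers, roles$outgroup)
      else length(v$carriers) > 0 && all(v$carriers %in% ingroup)
      v$branch %in% branches && identical(v$class, cls) && carriers_ok
    }, TRUE))
    data.frame(geneID = m$geneID, chrom = m$chrom,
               start = min(GenomicRanges::start(m$cds)),
               end = max(GenomicRanges::end(m$cds)),
               strand = m$strand, omega = m$omega, inRegion = m$inRegion,
               polyN = count(c("private", "killerA", "killerB"), "nonsyn"),
               polyS = count(c("private", "killerA", "killerB"), "syn"),
               divN = count("outgroup", "nonsyn"),
               divS = count("outgroup", "syn"),
               stringsAsFactors = FALSE)
  })
  list(region = list(chrom = p$regionChrom, start = p$regionStart,
                     end = p$regionEnd),
       tracts = p$tracts,
       samples = roles,
       genes = do.call(rbind, unname(gene_rows)),
       repeats = data.frame(
         chrom = as.character(GenomicRanges::seqnames(repeats)),
         start = GenomicRanges::start(repeats),
         end = GenomicRanges::end(repeats),
         family = repeats$family, stringsAsFactors = FALSE),
       seed = p$seed)
}

.writeSimFiles <- function(sim, p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- list(
    fasta = file.path(dir, "reference.fa"),
    vcf = file.path(dir, "variants.vcf"),
    gff = file.path(dir, "genes.gff3"),
    repeats = file.path(dir, "repeats.out"),
    methylation = file.path(dir, "methylation.bedGraph"),
    ip = file.path(dir, "ip.bedGraph"),
    input = file.path(dir, "input.bedGraph"),
    truth = file.path(dir, "truth.json"))
  writeGenome(sim$genome, f$fasta)
  writeVariants(sim$vm, f$vcf, refGenome = sim$genome)
  .writeGFF3(sim$models, f$gff)
  .writeRepeatMaskerOut(sim$repeats, f$repeats)
  m <- sim$methylation
  writeLines(paste(m$chrom, m$pos - 1L, m$pos,
                   sprintf("%.6g", 100 * m$frac), m$meth, m$total - m$meth,
                   sep = "\t"), f$methylation)
  wbg <- function(gr, path) {
    writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                     gr$score, sep = "\t"), path)
  }
  wbg(sim$ipCoverage, f$ip)
  wbg(sim$inputCoverage, f$input)
  truth <- sim$truth
  jsonlite::write_json(truth, f$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  f
}

.writeGFF3 <- function(models, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    s <- min(GenomicRanges::start(m$cds)); e <- max(GenomicRanges::end(m$cds))
    writeLines(sprintf("%s\tmeiodrive\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chrom, s, e, m$strand, m$geneID), con)
    mid <- paste0(m$geneID, ".t1")
    writeLines(sprintf("%s\tmeiodrive\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       m$chrom, s, e, m$strand, mid, m$geneID), con)
    for (k in seq_along(m$cds))
      writeLines(sprintf("%s\tmeiodrive\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                         m$chrom, GenomicRanges::start(m$cds)[k],
                         GenomicRanges::end(m$cds)[k], m$strand,
                         m$geneID, k, mid), con)
  }
  invisible(path)
}

.writeRepeatMaskerOut <- function(repeats, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin   end      (left)     repeat         class/family     begin  end    (left)   ID",
    ""), con)
  for (k in seq_along(repeats)) {
    writeLines(sprintf(" 1000   10.0  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
                       as.character(GenomicRanges::seqnames(repeats))[k],
                       GenomicRanges::start(repeats)[k],
                       GenomicRanges::end(repeats)[k],
                       repeats$family[k], repeats$class[k],
                       GenomicRanges::width(repeats)[k], k), con)
  }
  invisible(path)
}

#' Published McDonald-Kreitman count tables for the N. intermedia spore
#' killer dataset
#'
#' Returns the genome-wide and per-chromosome polymorphism/divergence counts
#' (PN, PS, DN, DS) reported for two Sk-2 strains of *Neurospora
#' intermedia* against the *N. metzenbergii* outgroup, as immutable
#' [MKTable-class] fixtures for regression tests of the ratio arithmetic:
#' Total, Chr1, Chr2, Chr3 (spore-killer region excluded), Chr7, and the Sk
#' region itself.
#'
#' @return Named list of [MKTable-class] objects.
#' @examples
#' round(neutralityIndex(skMKCounts()$SkRegion), 2)  # 1.27
#' @export
skMKCounts <- function() {
  list(
    Total = MKTable(58830, 153013, 59077, 132834, label = "Total"),
    Chr1 = MKTable(12349, 31767, 14403, 30655, label = "Chr1"),
    Chr2 = MKTable(6571, 17813, 6003, 13624, label = "Chr2"),
    Chr3 = MKTable(5293, 13168, 4897, 10775, label = "Chr3"),
    Chr7 = MKTable(7748, 18962, 7391, 15567, label = "Chr7"),
    SkRegion = MKTable(770, 1499, 2985, 7360, label = "SkRegion"))
}
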