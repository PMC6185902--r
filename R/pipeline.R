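#' Run the full drive-haplotype analysis pipeline
#'
#' Orchestrates: variant filtering, the monophyly scan of the region
#' chromosome, repeat/GC/methylation/ChIP window statistics with
#' repeat-family enrichment and the region-vs-genome confidence interval,
#' coding-sequence diversity/divergence aggregation with the
#' gene-resampling bootstrap, and (when a substitution rate is configured)
#' the age lower bound.  All tabular outputs are TSV, summaries JSON, and a
#' manifest records seed, package version and per-stage row counts.
#'
#' @param config A named list or the path to a YAML file.  Required fields:
#'   `fasta`, `vcf`, `gff`, `repeats` (paths), `focal`, `outgroup` (sample
#'   id vectors), `region` (`chrom`, `start`, `end`), `outdir`.  Optional:
#'   `methylation`, `ipCoverage`, `inputCoverage` (paths), `anchor`,
#'   `ingroup` (MK ingroup; default `focal`), `mkOutgroup` (default
#'   `outgroup`), `substitutionRate` (per site per year; enables the age
#'   stage), `sensitivePanel` (sample ids for the age bound; default all
#'   non-focal ingroup samples), and the window parameters
#'   `nSitesPerWindow` (50), `bin` (50), `windowSize` (2000), `windowStep`
#'   (2000), `divWindow` (10000), `divStep` (2000), `ciStep` (200000),
#'   `repeatThreshold` (0.75), `bootstrapReps` (1000), `scanReps` (100),
#'   `seed` (1).
#' @param stages Character vector of stages to run, a subset of
#'   `c("scan", "repeats", "chromatin", "molevol", "age")`.
#' @return Invisibly, the manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
runPipeline <- function(config,
                        stages = c("scan", "repeats", "chromatin", "molevol", "age")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .pipelineDefaults(config)
  stages <- match.arg(stages, several.ok = TRUE)

  ## ---- fail-fast validation before any compute ----
  for (f in c("fasta", "vcf", "gff", "repeats"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config error: missing input file for '", f, "'", call. = FALSE)
  if ("age" %in% stages && !is.null(cfg$requireAge) && isTRUE(cfg$requireAge) &&
      is.null(cfg$substitutionRate))
    stop("config error: age stage requested but no substitutionRate given",
         call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = "meiodrive",
                   version = as.character(utils::packageVersion("meiodrive")),
                   seed = cfg$seed, stages = list())
  mpath <- file.path(cfg$outdir, "manifest.json")
  fail <- function(stage, e) {
    manifest$status <- paste0("failed at ", stage)
    jsonlite::write_json(manifest, paste0(mpath, ".partial"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  genome <- readGenome(cfg$fasta)
  seqlen <- setNames(Biostrings::width(genome), names(genome))
  vm <- readVariants(cfg$vcf)
  repeats <- readRepeatMasker(cfg$repeats, seqlengths = seqlen)
  models <- readGeneModels(cfg$gff, seqlengths = seqlen)
  region <- GenomicRanges::GRanges(cfg$region$chrom,
                                   IRanges::IRanges(cfg$region$start,
                                                    cfg$region$end))
  if (!cfg$region$chrom %in% names(genome))
    stop("config error: region chromosome not in genome", call. = FALSE)
  missing_samples <- setdiff(c(cfg$focal, cfg$outgroup, cfg$anchor),
                             sampleNames(vm))
  if (length(missing_samples))
    stop("config error: sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)

  vmF <- filterVariants(vm, repeats)
  manifest$stages$filter <- list(sitesBefore = sum(vapply(chromNames(vm),
                                   function(ch) nSites(vm, ch), 0L)),
                                 sitesAfter = sum(vapply(chromNames(vmF),
                                   function(ch) nSites(vmF, ch), 0L)))

  if ("scan" %in% stages) tryCatch({
    scan <- scanChromosome(vmF, cfg$region$chrom, cfg$focal, cfg$outgroup,
                           nSitesPerWindow = cfg$nSitesPerWindow,
                           reps = cfg$scanReps, bin = cfg$bin,
                           anchor = cfg$anchor,
                           seed = .childSeed(cfg$seed, 1L))
    calls_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(scan$calls)),
      start = GenomicRanges::start(scan$calls),
      end = GenomicRanges::end(scan$calls),
      category = scan$calls$category, support = scan$calls$support)
    write.table(calls_df, file.path(cfg$outdir, "monophyly_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scan$bins, file.path(cfg$outdir, "monophyly_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$scan <- list(windows = nrow(calls_df),
                                 bins = length(unique(scan$bins$bin)))
    if (!is.null(cfg$divergencePair)) {
      div <- pairwiseDivergenceScan(vmF, cfg$region$chrom,
                                    cfg$divergencePair[1], cfg$divergencePair[2],
                                    windowSize = cfg$divWindow,
                                    step = cfg$divStep,
                                    chromLength = seqlen[[cfg$region$chrom]])
      write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(div)),
                             start = GenomicRanges::start(div),
                             end = GenomicRanges::end(div),
                             divergence = div$divergence),
                  file.path(cfg$outdir, "pairwise_divergence.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$scan$divergenceWindows <- length(div)
    }
  }, error = function(e) fail("scan", e))

  windows <- NULL
  if (any(c("repeats", "chromatin") %in% stages)) {
    windows <- unlist(GenomicRanges::GRangesList(lapply(names(genome),
      function(ch) fixedWindows(seqlen[[ch]], cfg$windowSize, cfg$windowStep,
                                chrom = ch))))
    windows$repeatFraction <- windowRepeatFraction(windows, repeats)
    windows$class <- classifyRepeatWindows(windows$repeatFraction,
                                           cfg$repeatThreshold)
    windows$gc <- windowGC(genome, windows)
  }

  if ("repeats" %in% stages) tryCatch({
    in_region <- IRanges::overlapsAny(windows, region)
    enr <- familyEnrichment(
      IRanges::subsetByOverlaps(repeats, region), repeats,
      regionLength = GenomicRanges::width(region),
      genomeLength = sum(seqlen))
    jsonlite::write_json(enr, file.path(cfg$outdir, "family_enrichment.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    region_len <- GenomicRanges::width(region)
    slide <- fixedWindows(seqlen[[cfg$region$chrom]], region_len,
                          min(cfg$ciStep, max(1L, seqlen[[cfg$region$chrom]] - region_len)),
                          chrom = cfg$region$chrom)
    for (ch in setdiff(names(genome), cfg$region$chrom))
      if (seqlen[[ch]] >= region_len)
        slide <- c(slide, fixedWindows(seqlen[[ch]], region_len, cfg$ciStep,
                                       chrom = ch))
    rv <- windowRepeatFraction(slide, repeats)
    region_frac <- windowRepeatFraction(region, repeats)
    ci <- tryCatch(regionVsGenomeCI(rv, region_frac),
                   error = function(e) list(note = conditionMessage(e)))
    jsonlite::write_json(ci, file.path(cfg$outdir, "region_repeat_ci.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$repeats <- list(familiesTested = nrow(enr),
                                    regionRepeatFraction = region_frac)
  }, error = function(e) fail("repeats", e))

  if ("chromatin" %in% stages) tryCatch({
    if (!is.null(cfg$methylation)) {
      meth <- readMethylation(cfg$methylation, seqlengths = seqlen)
      windows$methylationPct <- windowMethylation(meth, windows)
    }
    if (!is.null(cfg$ipCoverage) && !is.null(cfg$inputCoverage)) {
      ip <- readCoverage(cfg$ipCoverage)
      input <- readCoverage(cfg$inputCoverage)
      windows$chipFold <- chipFold(ip, input, windows, seqlen)
    }
    comp <- list()
    for (col in intersect(c("gc", "methylationPct", "chipFold"),
                          names(S4Vectors::mcols(windows)))) {
      v <- S4Vectors::mcols(windows)[[col]]
      a <- v[windows$class == "repeat"]; b <- v[windows$class == "non_repeat"]
      if (sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2) {
        cg <- compareGroups(a, b)
        comp[[col]] <- list(t = cg$statistic, p = cg$p.value,
                            meanRepeat = unname(cg$ciA["mean"]),
                            meanNonRepeat = unname(cg$ciB["mean"]))
      }
    }
    jsonlite::write_json(comp, file.path(cfg$outdir, "group_comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$chromatin <- list(windows = length(windows),
                                      comparisons = names(comp))
  }, error = function(e) fail("chromatin", e))

  if (!is.null(windows)) {
    wt <- data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
                     start = GenomicRanges::start(windows),
                     end = GenomicRanges::end(windows),
                     as.data.frame(S4Vectors::mcols(windows)))
    write.table(wt, file.path(cfg$outdir, "window_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("molevol" %in% stages) tryCatch({
    ingroup <- if (!is.null(cfg$ingroup)) cfg$ingroup else cfg$focal
    mk_out <- if (!is.null(cfg$mkOutgroup)) cfg$mkOutgroup else cfg$outgroup
    alns <- buildCodonAlignments(genome, vm, models, ingroup, mk_out)
    ok <- vapply(alns, function(a) a@valid && length(a@ingroup) >= 2, TRUE)
    stats <- lapply(alns[ok], geneStats)
    part <- genePartition(models[names(alns)[ok]], region)
    agg <- aggregateGenes(stats, part)
    write.table(agg, file.path(cfg$outdir, "molevol_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$molevol <- list(genes = sum(ok),
                                    partitions = nrow(agg))
    if ("region" %in% part && sum(part != "region") >= 1) {
      region_row <- agg[agg$partition == "region", ]
      observed <- c(PN = region_row$PN, PS = region_row$PS,
                    DN = region_row$DN, DS = region_row$DS,
                    piN = region_row$piN, piS = region_row$piS,
                    piNpiS = region_row$piNpiS, PN_PS = region_row$PN_PS,
                    DN_DS = region_row$DN_DS, NI = region_row$NI)
      bn <- bootstrapNull(stats[part != "region"],
                          nRegionGenes = sum(part == "region"),
                          regionLength = region_row$totalLength,
                          observed = observed,
                          reps = cfg$bootstrapReps,
                          seed = .childSeed(cfg$seed, 2L))
      bn_out <- lapply(bn, function(x) x[c("observed", "mean", "lower",
                                           "upper", "p")])
      jsonlite::write_json(bn_out, file.path(cfg$outdir, "bootstrap_null.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$stages$molevol$bootstrapReps <- cfg$bootstrapReps
    }
  }, error = function(e) fail("molevol", e))

  if ("age" %in% stages && !is.null(cfg$substitutionRate)) tryCatch({
    panel <- if (!is.null(cfg$sensitivePanel)) cfg$sensitivePanel else
      setdiff(sampleNames(vm), c(cfg$focal, cfg$outgroup, cfg$anchor))
    region_models <- models[genePartition(models, region) == "region"]
    alns <- buildCodonAlignments(genome, vm, region_models,
                                 ingroup = cfg$focal[1], outgroup = panel)
    alns <- Filter(function(a) a@valid, alns)
    age <- ageLowerBound(alns, cfg$substitutionRate)
    jsonlite::write_json(age[c("pooledDS", "ratePerYear", "ageYears")],
                         file.path(cfg$outdir, "age_bound.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$age <- list(genes = nrow(age$perGene),
                                ageYears = age$ageYears)
  }, error = function(e) fail("age", e))

  manifest$status <- "ok"
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.pipelineDefaults <- function(cfg) {
  defaults <- list(nSitesPerWindow = 50L, bin = 50L,
                   windowSize = 2000L, windowStep = 2000L,
                   divWindow = 10000L, divStep = 2000L,
                   ciStep = 200000L, repeatThreshold = 0.75,
                   bootstrapReps = 1000L, scanReps = 100L, seed = 1L,
                   anchor = NULL, outdir = "meiodrive_out")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}
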