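Package: meiodrive
Title: Genomic Analysis of Non-Recombining Meiotic Drive Haplotypes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based genomic analyses for characterizing large
    non-recombining haplotypes such as fungal spore-killer (meiotic drive)
    regions. Provides sliding-window BioNJ tree construction and monophyly
    classification to detect recombination and introgression tracts from
    haploid SNP matrices; window-level repeat, GC, cytosine-methylation and
    ChIP fold-enrichment statistics with repeat-family enrichment tests and
    region-versus-genome confidence intervals; Nei-Gojobori style
    synonymous/nonsynonymous diversity and divergence, McDonald-Kreitman
    tables, the neutrality index, a gene-resampling bootstrap null, and a
    minimum-synonymous-divergence age bound; plus a seeded synthetic-data
    generator that emits standard formats together with a ground-truth record.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, PopulationGenetics, Epigenetics,
    Software
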