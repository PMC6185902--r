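---
title: "Analysing non-recombining meiotic-drive haplotypes with meiodrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing non-recombining meiotic-drive haplotypes with meiodrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodrive)
```

## The scientific problem

Meiotic drive elements such as the *Neurospora intermedia* spore killers
*Sk-2* and *Sk-3* occupy multi-megabase chromosomal haplotypes in which
recombination with sensitive strains is suppressed, typically by stacked
inversions. Three signatures follow from that suppression, and this package
implements the window-based procedures used to measure each of them from
standard population-genomic inputs (FASTA, haploid VCF, GFF3, RepeatMasker
annotations, bedGraph tracks):

1. **Local genealogy**: in the absence of recombination, the killer strains
   form a monophyletic group in every genomic window; an introgression
   (double-crossover) tract shows up as a run of windows where one strain
   drops out of the clade.
2. **Repeat and heterochromatin landscape**: relaxed purging lets
   transposable elements accumulate, producing low-GC, cytosine-methylated,
   H3K9me3-marked repeat clusters.
3. **Molecular degeneration**: reduced effective recombination weakens
   purifying selection, visible as an elevated
   $\pi_N/\pi_S$ ratio and a McDonald--Kreitman neutrality index above 1.

## Window monophyly scan

SNPs are first cleaned the way the upstream pipeline defines the usable
matrix: every site inside a repeat annotation and every site with a missing
call in *any* sample is removed (`filterVariants()`). The remaining variable
sites on a chromosome are split into consecutive, non-overlapping windows of
exactly 50 sites (`variableSiteWindows()`); a trailing partial window is
dropped rather than analysed with less information, and the count is
reported.

Within each window:

* `pDistance()` computes pairwise p-distances $d_{ij}$ = (differing sites) /
  (window sites). The variance matrix required by the BioNJ weighting is
  initialized to the distance itself, the natural choice when every window
  has the same number of sites. A Jukes--Cantor correction is available
  (`correction = "JC69"`) but off by default: 50-site windows between
  closely related haploid strains sit far from saturation, and the transform
  is undefined at $p \ge 3/4$.
* `bionjTree()` builds the tree by variance-weighted neighbour joining.
  At each step the pair minimizing $Q(i,j) = (r-2)\,d_{ij} - S_i - S_j$ is
  joined; reduced distances and variances mix the two members with weight
  $\lambda = 1/2 + \sum_k (v_{jk} - v_{ik}) / (2(r-2)v_{ij})$, clamped to
  $[0,1]$, with $\lambda = 1/2$ when $v_{ij} = 0$ or three nodes remain.
  Ties in the pair choice are broken by the smallest index pair so results
  are platform-independent. Negative branch-length estimates are clamped to
  zero in the reported tree only; the raw estimates drive the reduction, as
  in classic neighbour joining. A subtlety worth recording: $\lambda$ is
  scale-invariant in the variances, and the reduction shrinks new-node
  variances relative to the originals, so a constant *positive* variance
  matrix does not stay at $\lambda = 1/2$ after the first join. The
  "uninformative variances" route to plain NJ is the all-zero variance
  matrix, which is what the equivalence tests use.
* `rootOnOutgroup()` roots the window tree on the designated outgroup set
  (in the spore-killer setting, the *N. metzenbergii* strains). The source
  analyses do not state a rooting rule; monophyly is only defined on a
  rooted tree, and an outgroup root is the standard choice. When the
  outgroup is a clade the root bisects its stem edge; otherwise the tree is
  rooted on the terminal edge of the first outgroup id — a deterministic,
  logged fallback.
* `classifyGrouping()` reports which focal (killer) strains group together:
  the leaf set of the largest clade whose leaves are a non-empty subset of
  the focal set. When two equal-sized exclusively-focal clades exist the
  lexicographically smallest sorted id tuple is reported; this tie-break is
  a convention of this package, chosen only for determinism. With an
  `anchor` sample (scanning which killer-A strains join the single killer-B
  strain), the category is the focal content of the smallest clade
  containing the anchor whose leaves all lie in focal $\cup$ anchor.
* `bootstrapSupport()` resamples the window's sites with replacement,
  rebuilds the tree, and reports the fraction of replicates reproducing the
  *originally identified* category — support for that group, not for the
  best group per replicate. The default is 100 replicates, each window
  drawing its own seeded stream derived from (global seed, window index),
  so stage-level reruns reproduce pipeline-level results.

`scanChromosome()` strings these together and summarizes category
proportions in bins of 50 consecutive windows (the final partial bin is
reported at its actual size; proportions sum to one within each bin).
`pairwiseDivergenceScan()` provides the companion track: differences per bp
between two named samples in 10 kb windows at a 2 kb step.

## Repeat, GC, methylation and ChIP windows

Fixed 2 kb non-overlapping windows (`fixedWindows()`, emitted only when they
fit entirely on the chromosome) carry the landscape statistics:

* `windowRepeatFraction()` merges overlapping annotations before counting,
  so the value is union coverage and order-independent.
* `classifyRepeatWindows()` labels a window *repeat* strictly above 75%
  repeat content; exactly 75% is non-repeat.
* `windowMethylation()` needs a per-site call; bisulfite reports give
  (methylated, total) read counts. A covered cytosine is called methylated
  at a methylated-read fraction of at least 0.5 (configurable), and the
  window value is the percentage of called sites. A read-weighted
  alternative (sum methylated / sum total reads) is provided; windows with
  no covered cytosine are undefined and excluded from group means.
* `chipFold()` is mean immunoprecipitated depth over mean input depth per
  window, undefined where the input mean is zero.
* `compareGroups()` is a pooled-variance Student's t test (the test named by
  the source analyses; Welch via a flag), returning each group's mean with
  a $\pm 1.96\,\mathrm{SE}$ interval for plotting. Zero pooled variance with
  equal means yields $t = 0, p = 1$; with unequal means the result is
  flagged degenerate with $p = 0$.
* `familyEnrichment()` tests each repeat family with a one-sided binomial
  upper tail $P(X \ge k \mid n, p_0)$, Bonferroni-corrected across the
  families tested. The trial unit is base pairs by default — enrichment is
  reported as percentages of sequence — with annotation counts as an
  option; base pairs are not independent trials, so the p-values are
  honest ranks rather than calibrated probabilities, and the output is
  labelled with the unit used.
* `regionVsGenomeCI()` compares a region statistic against windows of the
  region's own size slid across the genome (200 kb step), reporting the
  2.5th/97.5th empirical percentiles with linear interpolation. Whether the
  original error bars were percentile or parametric is not stated; the
  empirical choice makes no distributional assumption and is recorded in
  the output metadata.

## Coding-sequence diversity, divergence and the MK framework

CDS haplotypes are reconstructed by substituting each sample's alleles into
the reference CDS, splicing exons and reverse-complementing minus-strand
genes (`buildCodonAlignments()`); genes whose spliced length is off-frame or
that contain internal stops are flagged invalid and skipped. Identical
ingroup haplotypes can be collapsed first (`dedupHaplotypes()`), mirroring
analyses that select distinct haplotypes.

Counting follows Nei--Gojobori (1986) equal-pathway conventions — the
original analyses used an external program with unpublished internals, so
this package adopts the documented standard and verifies against printed
ratio arithmetic rather than against that program's site counts:

* `ng86SiteCounts()`: per codon position, the synonymous fraction of the
  three single-nucleotide mutants, with mutations to stop codons excluded
  from the denominator; summed over positions, and $N = 3 - S$.
* `pairwiseCodonDiffs()`: synonymous/nonsynonymous change counts averaged
  over all minimal mutational pathways, pathways through stops excluded
  (if every pathway is blocked, all are used with stop steps counted
  nonsynonymous). The counts always sum to the Hamming distance.
* `geneDiversity()`: $\pi_N$ and $\pi_S$ as means over ingroup pairs of
  (differences / sites), sites averaged within each pair; codons with stops
  or ambiguity in either member are excluded for that pair.
* `genePolymorphism()` counts segregating changes per codon column from the
  distinct codons present (averaged over distinct pairs — exact for the
  two-haplotype ingroup used in the motivating study and in the simulated
  default). `geneDivergence()` counts only *fixed* differences: all ingroup
  sequences share one sense codon, all outgroup sequences another —
  standard MK practice; columns polymorphic in either group contribute to
  polymorphism instead.
* `aggregateGenes()` pools a partition (chromosome, or the drive region
  "treated as a whole chromosome"): P/D counts are summed, $\pi$ values are
  pooled length-weighted as $\sum$ differences / $\sum$ sites — equivalent
  to a concatenated-alignment computation — and the neutrality index
  $\mathrm{NI} = (P_N/P_S)/(D_N/D_S)$ is computed on pooled counts. Genes
  straddling the region boundary are assigned by CDS midpoint, with a note.
* `bootstrapNull()` draws the region's gene count with replacement from the
  background genes; count statistics are rescaled by region length / total
  sampled gene length, ratio statistics are unscaled; the interval is the
  2.5/97.5 percentile pair and the two-sided empirical p-value is
  $2\min(r, 1-r)$ with $r = (1 + \#\{\text{reps} \le \text{obs}\})/(\text{reps}+1)$.
* `ageLowerBound()`: because the sensitive strains recombine freely, no
  single strain is the killer haplotype's closest relative; per gene the
  panel member with minimum synonymous divergence is chosen, the
  minimizing partners' synonymous differences and sites are pooled, and the
  age bound is pooled $d_S / (2\mu)$. The substitution rate $\mu$ is a
  required parameter with no default — it is a property of the study
  system, not of the method. Pooled (rather than mean or median) $d_S$ was
  chosen for consistency with the length-weighted pooling used everywhere
  else.

`skMKCounts()` stores the published genome-wide, per-chromosome and
Sk-region (P~N~, P~S~, D~N~, D~S~) count tables as immutable fixtures; the
ratio arithmetic on them is the package's primary regression surface:

```{r}
round(neutralityIndex(skMKCounts()$SkRegion), 2)
round(neutralityIndex(skMKCounts()$Total), 2)
round(mkRatios(skMKCounts()$Total), 2)
```

## The synthetic-data generator

`simulateDriveData()` emits a complete toy dataset — reference FASTA,
haploid VCF, GFF3, RepeatMasker-style table, methylation and ChIP/input
bedGraphs, plus a machine-readable truth record — with the statistical
structure the analyses assume:

* a **star genealogy** for the sensitive strains (each sample receives
  private Poisson mutations at depth $\theta$, so two sensitives differ at
  $\approx 2\theta$ per site);
* a **killer clade** whose stem mutations span the configured region,
  making the focal strains monophyletic there; a second, independent killer
  lineage plays the anchor role;
* an **outgroup** clade at its own depth, genome-wide;
* **recombination tracts** that replace a named killer sample's region
  haplotype with the sensitive consensus over an interval;
* **repeat clusters** drawn at GC 0.30 against a 0.50 background, carrying
  high methylated-read fractions and elevated IP coverage;
* **genes** built as clean ORFs whose mutations are placed codon-by-codon
  with the synonymous/nonsynonymous mix controlled by a per-gene
  $\omega$: at $\omega = 0$ coding variation is purely synonymous, so
  planted $\pi_N$ is exactly zero; at most one mutation per codon is
  planted, so per-gene (P~N~, P~S~, D~N~, D~S~) in the truth record are
  recovered *exactly* by the counting machinery.

No coalescent machinery is used: fixed genealogies with Poisson mutation
counts keep every expectation analytic, which is the right trade-off when
the object under test is procedure recovery rather than population-genetic
realism. Consequently the generator does **not** emulate coalescent
genealogy variance among sensitive strains, linkage disequilibrium decay,
indels or structural variation, RIP-style mutation bias inside repeats, or
read-level noise — so green tests certify the *procedures* (windowing, tree
building, classification, counting, pooling, rescaling), not robustness to
those properties of real data.

Default conditions (one 100 kb background chromosome, one 300 kb chromosome
carrying a 160 kb region, 8 sensitive / 4 focal killer / 1 anchor killer /
5 outgroup samples, $\theta = 0.004$, killer split 0.02, outgroup depth
0.05) were chosen once to mirror the motivating study's design at desk
scale. The scan-level test fixtures use a single 50 kb region chromosome
with 13 samples, giving roughly 5,000 variable sites (about 100 windows) per
replicate; tract-recovery and coverage checks run 100–200 seeded replicates
at that size.

## Numerical and convention notes

* Coordinates are 1-based, closed intervals internally — the
  Bioconductor/GRanges convention — with 0-based half-open conversion
  handled at the BED/bedGraph boundaries by the standard readers. Keeping
  one convention across every container the package passes around beats
  carrying two.
* Multi-allelic SNPs and indels are dropped at VCF read time (logged);
  "missing anywhere → site removed" is applied globally, matching the
  upstream cleaning rule.
* Degenerate windows (all sequences identical) yield an empty category with
  undefined support rather than an arbitrary singleton.
* All simulation, bootstrap and scan randomness flows from explicit integer
  seeds through a single child-seed scheme kept inside 32-bit range.

## Known limitations

* The binomial enrichment unit (bp) ignores spatial autocorrelation of
  repeats; treat small p-values as rankings.
* Polymorphism counting averages over distinct codon pairs when more than
  two distinct codons segregate at a column; with more than ~4 ingroup
  haplotypes a frequency-weighted scheme would be preferable.
* The monophyly scan classifies windows independently; it does not smooth
  across windows, so single-window misclassifications near tract boundaries
  are expected (the planted-tract tests allow one window of slack).
* `bootstrapNull()` resamples genes, not sites, so within-gene linkage is
  preserved but gene-level variance drives the intervals — matching the
  original design, but intervals will be anti-conservative if a few long
  genes dominate a partition.
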