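---
title: "Mapping bacterial transcription units from RNA end profiles"
author: "tumapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial transcription units from RNA end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumapr)
```

## The problem

A bacterial transcriptome map answers three questions at single-nucleotide
resolution: where does transcription start (TSSs), where do transcripts end
(TEPs), and which genes travel together on one mRNA (transcription units,
TUs). Two complementary end-capture assays provide the raw signal. dRNA-seq
compares a terminator-exonuclease (TEX) treated library, in which processed
5' ends are degraded, against an untreated library: genuine transcription
start sites appear as 5'-end peaks enriched in the treated library. Term-seq
captures transcript 3' termini, so transcript end positions appear as
3'-end peaks. Conventional RNA-seq coverage ties the two together and
measures how much transcription leaks past each terminator.

`tumapr` implements this mapping as a reusable pipeline for high-GC
bacterial genomes (the motivating organism is an alphaproteobacterial
methanotroph with ~65% GC), starting from strand-specific per-position
end-count tracks (bedGraph), a genome (FASTA) and a gene annotation (GFF3).
Because the assays themselves are rarely rerun, the package also ships a
deterministic simulator that plants known sites into a synthetic genome so
that every stage of the pipeline can be validated against ground truth.

## Site calling and classification

A position is called as a TSS when its TEX-treated 5'-end count reaches
`min_height` (default 10), its pseudocounted enrichment ratio
(enriched + 1)/(unenriched + 1) reaches `min_enrichment` (default 2), and
it is the maximum of its +/-2 nt neighbourhood (ties resolved to the
5'-most position). TEPs use the same local-maximum rule on the Term-seq
3'-end track, with ties resolved to the 3'-most position. The pseudocount
handles zero counts in the untreated library; the local-maximum filter
collapses the 1-2 nt jitter that end-capture chemistry produces around a
true site.

Sites called in different growth conditions are merged by single-linkage
clustering within +/-5 nt per strand; the merged record sits at the
position with the highest summed count and carries the union of condition
labels, so a site found in every condition is flagged constitutive.
Merging is idempotent: merging an already-merged list changes nothing,
because representatives of distinct clusters are by construction more than
5 nt apart.

Merged sites are classified against the annotation. For TSSs, sites within
300 nt upstream of a gene start on its own strand compete: the highest
becomes the primary (P) TSS, the rest secondary (S); remaining sites inside
a sense-strand gene body are internal (I), sites within a gene body or its
+/-100 nt flanks on the opposite strand antisense (A), and everything else
intergenic (N). The 300-nt window is a deliberate choice: the assay
literature for 3' ends fixes 300 nt as the primary-TEP window, and we use
the same span upstream for symmetry. Ties between two candidate genes go to
the nearer start, then to the lexicographically smaller gene identifier, so
results are reproducible. 5'-UTR length is the distance from the
transcribed +1 base to the gene start; transcripts with a 5'-UTR under
10 nt are flagged leaderless, 10 nt being too short to hold a
ribosome-binding site upstream of the start codon.

TEP classification mirrors this: sites within 300 nt downstream of a gene
3'-end compete for primary (P) / secondary (S); sites inside a mapped
primary-TSS 5'-UTR are cis-regulatory (C) -- candidate premature
termination or riboswitch read-off ends; antisense (A) uses gene-body
overlap only; the rest are intergenic (N). A gene without a mapped primary
TSS cannot host a C TEP; this is conservative but keeps the C class
interpretable. Categories always partition the site list, and the package
asserts this on every run.

## Terminator typing

Intrinsic (Rho-independent) terminators are RNA hairpins. The classical
L-shaped terminator follows its hairpin with a run of uridines; I-shaped
terminators, common in high-GC genomes, lack the U-tract. The pipeline
folds the 40-nt window ending at each TEP on the transcript strand and
splits TEPs into highly structured (HS) and less structured (LS) at a free
energy threshold, then types HS TEPs by the number of uridines in the
10 nt following the stem-loop (>= 3 U: `HS_U_RICH`, i.e. L-shaped;
otherwise `HS_U_LACK`, I-shaped).

The folder is an in-package Zuker-style dynamic program over nested
structures with a compact nearest-neighbor model: published Watson-Crick
stack free energies and enthalpies at the 37 degree reference, a simplified
class-based parameterization for G:U wobble stacks, tabulated hairpin,
bulge and internal-loop penalties with logarithmic extrapolation, an affine
multibranch-loop term, a minimum hairpin loop of 3 nt, and no dangling
ends, coaxial stacking or helix-end terms. Temperature (default 30 degrees
C) enters by recomputing stack free energies from the enthalpies and
scaling loop penalties as purely entropic. The model is deliberately small
enough to be verified exactly: `fold_enumerate()` walks *every* nested
structure of a sequence by depth-first search with sound branch-and-bound
pruning (a branch is discarded only when an admissible relaxed-score bound
proves no completion can beat the incumbent), and the test suite checks
that the dynamic program and this enumeration agree to numerical precision
on hundreds of random 20-40 nt sequences.

Because the energy table is not the one used by mainstream folding engines,
absolute free energies differ from published values by a few kcal/mol. The
HS/LS threshold therefore defaults to the *median* of the observed delta G
distribution -- the same definition used to derive the -19 kcal/mol split
in the motivating organism -- rather than a hard-coded constant; a fixed
threshold can be supplied when comparing against an external folding
engine. The "following the stem-loop" anchor is the 3'-most paired base of
the continuous helix closing the 3'-most hairpin loop; bulges interrupt a
helix, so a bulged stem anchors at its inner continuous segment.

Readthrough is quantified from RNA-seq coverage as the mean over the 200 nt
downstream of the TEP divided by the mean over the 200 nt upstream
(transcript-strand oriented). This orientation makes the statistic a
leakage fraction: a strong terminator scores near 0, absence of termination
near 1. Per-class summaries exclude fractions above the 95th percentile of
the pooled distribution, removing sites where a downstream TU inflates the
ratio; exclusion is applied to the pooled rather than per-class
distribution so that classes remain comparable.

## Transcription units

Each TSS is paired with the nearest downstream TEP on its strand, provided
the TEP lies within 15 kb (a generous bound for bacterial operons) and
does not cross into the gene block of the next primary TSS. The region
between the two endpoints is the TU; genes fully contained on the sense
strand define its category (monocistronic, polycistronic), and gene-less
TUs inherit cis-regulatory or intergenic status from their TEP. TUs
assembled per condition merge when both endpoints agree within +/-5 nt.
The pairing rule is this package's design -- end-capture assays define
only "the region between a TSS and a TEP" -- and the next-gene-block guard
is what prevents a strong promoter from swallowing its downstream
neighbour when a condition-specific terminator is absent from one library.

Functional relatedness of co-transcribed genes is scored per TU as the
maximum number of member genes sharing one COG category divided by the
number of distinct categories present (genes without a category excluded).
This literal ratio can exceed 1 when all genes share a category; a
`per_gene` mode normalizing by gene count (bounded by 1) is provided
because the literal definition is ambiguous on that point. The observed
score distribution is compared against size-matched runs of consecutive
same-strand genes drawn at random ("random neighbour" baseline) with a
two-sided Mann-Whitney test.

## What the simulator emulates -- and what it does not

`simulate_genome()` plants operons along an i.i.d. background genome at a
configurable GC fraction (default 0.65). Each operon receives one TSS
20-300 nt upstream of its first gene, with the transcribed +1 base drawn
purine with probability 0.86 (the observed initiation preference in
bacterial dRNA-seq maps), and one terminator: L-shaped (GC-only stem of
8-12 bp, loop 4-8 nt, U-tract of 4-8 nt ending at the TEP), I-shaped (the
same stem-loop with an enforced U-poor tail, <= 2 U in the 10 nt after the
stem), or unstructured (a TEP placed in plain background sequence). GC-only
stems guarantee a wide free-energy gap between planted hairpins and
anything the 65%-GC background folds into; empirically planted windows
fold below -19 kcal/mol while background windows stay above -16. Shape
classes are planted as a stratified, shuffled multiset matching the
configured mix (default 15% L / 35% I / 50% unstructured, the proportions
observed in the motivating genome) rather than sampled independently --
with a median-based HS/LS split, the split can only track the planted
classes if the structured fraction matches the mix up to rounding, and
binomial drift at 60 sites would otherwise push unstructured sites into HS
by force of arithmetic.

`simulate_libraries()` generates, per condition and replicate, Poisson
end-count tracks: background (default 0.1 counts/nt) everywhere, plus
peaks of mean height 300 at active planted sites; the untreated dRNA track
carries the same peaks attenuated by the TEX enrichment factor (default
8-fold). RNA-seq coverage is piecewise constant along each TU with a
shape-dependent fraction (5% / 10% / 50%) leaking 200 nt past the
terminator. The default peak height is a power choice: with 100 kb, 60
sites and background 0.1, the replicate Pearson correlation over the
nonzero-position union is approximately spatial-signal variance over
(signal + Poisson noise), and peaks of 300 put the expected r near 0.99
with seed-to-seed minima above 0.985, matching the reproducibility regime
(r > 0.98) of the assays being emulated; peaks of order 100 would leave r
hovering at the boundary. Condition-specific sites are simulated by
zeroing the peak term in the other condition.

The simulator does *not* emulate: read-level artifacts (mapping bias,
multimapping, rRNA carry-over), overdispersed counts (Poisson only),
processed 5' ends that survive TEX digestion, overlapping or nested
operons, Rho-dependent termination, or condition-dependent expression
levels. Passing the recovery benchmarks therefore demonstrates that the
callers and classifiers implement their rules correctly at realistic
signal-to-noise, not that the thresholds are optimal for any particular
real dataset.

## Benchmark sizes and numerical choices

The validation suite runs the simulator at its defaults: one 100 kb contig,
60 genes, two conditions, two replicates, seed fixed. At this size the
full pipeline (calling, merging, classification, 60 foldings, readthrough,
TU assembly) completes in a few seconds, and planted-site recovery,
shape recovery, readthrough ordering and replicate correlation are all
measured from one end-to-end run. The folder-vs-enumeration check uses 200
random sequences of 20-40 nt with uniform base composition. The
operon-relatedness benchmark uses a larger layout
(800 kb, 330 genes in operons of 2-4) so that at least 100 polycistronic
TUs feed the Mann-Whitney comparison. A random 40-mer admits on the order
of 1e8 nested structures, so the enumeration check runs from seconds to a
few minutes per 200-sequence batch depending on how the draws land; the
pruned search remains exact throughout, and its pruning is itself verified
against unpruned enumeration on short sequences where the full walk is
feasible. A third, structurally independent check re-scores each reported
structure by explicit loop decomposition and compares it with the reported
free energy.

Numerical details worth knowing: enrichment ratios use a pseudocount of 1;
energies are compared with a 1e-6 kcal/mol tolerance (both folder and
enumeration accumulate the same table in different orders); the HS/LS
split is inclusive at the threshold (delta G equal to the threshold is
HS), so with the median rule an odd-sized TEP set puts ceiling(n/2) sites
in HS; site-call ties break 5'-most for TSSs and 3'-most for TEPs;
degenerate inputs (empty site lists, constant profiles, zero upstream
coverage) raise informative errors or are excluded and counted, never
silently dropped.

## Known limitations

The energy model omits dangles, coaxial stacking, special hairpin loops
and lone-pair penalties, so its delta G values should be compared only
against its own enumeration oracle or used through the median-threshold
rule. Classification windows (300 nt, 100 nt flanks, 10 nt leaderless
bound) are biological conventions, not fitted parameters. The TU
assembler pairs each TSS with a single TEP; genuine multi-terminator
operons with internal processing sites collapse to their proximal
terminator. COG categories are single-letter; multi-category genes are not
supported.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_genome(cfg)
libs <- simulate_libraries(sim$annotation, sim$truth, cfg)
res <- run_tu_pipeline(sim$annotation, libs)

table(res$tss$category)
table(res$tep$shape)
res$readthrough$summary
res$tu_summary
recovery_stats(res$tss, sim$truth$tss)
```
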