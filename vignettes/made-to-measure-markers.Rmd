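---
title: "Made-to-measure markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Made-to-measure markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerforge)
```

## The problem

Phylogenetic inference in rapid radiations needs many long, independent,
single-copy nuclear markers.  Hybrid-enrichment ("sequence capture")
delivers them, but baits are a major cost, and bait-to-target
hybridisation tolerates only about 25% divergence, so the marker set must
be tailored to the focal clade.  `markerforge` implements a two-stage
custom marker-selection workflow plus the downstream processing of
captured contigs:

1. **Discovery** — find homologues shared by at least two transcriptomes,
   remove multi-copy genes (against whole-genome data where available,
   otherwise against a single-copy gene catalogue), apply a 75% identity
   floor, and infer exon/intron structure by spliced mapping to the
   genome.
2. **Selection** — rank the candidate pool by exon length, by predicted
   exon-plus-intron length, or by variability, exclude exons shorter than
   a bait from targeting, and greedily pick the best markers that fit a
   fixed bait budget (by default 5,770 baits of 120 bp at 4x tiling:
   692,400 bp of baits, a 173,100 bp capture footprint).
3. **Post-processing** — match assembled contigs back to targets, merge
   compatible contigs with IUPAC ambiguity coding, filter alignment
   columns with indels or missing data, and report percent variable
   sites per marker.

## The homology engine

All similarity decisions run through one engine: a k-mer seeded local
search (seed length 11) whose seed clusters are realigned with an exact
Smith–Waterman (Gotoh) aligner inside a padded window, so reported hits
are exact local optima of the scoring scheme (match +1, mismatch −1, the
first base of a gap −2, each further base −1).  Identity is defined as
matches over alignment columns *including gaps* — the convention of the
BLAST family this engine stands in for — and ambiguity codes (including
N) never match anything, a deliberately conservative choice since a
capture probe cannot pair with an unknown base.  Full-length comparisons
(the 75% similarity filter between cluster members) use global alignment
with penalised end gaps.  E-values are not computed: every decision in
the workflow is phrased in identity and length terms.

Sensitivity: a planted homologue is found whenever any exact 11-mer
survives between the copies and the seed window (±200 bp padding) covers
it.  At the 0.75 identity floor an 11-mer survives a given position with
probability $0.75^{11} \approx 0.042$, so for homologues of a few hundred
bases the miss probability is far below $10^{-3}$; the test suite checks
seeded/exact agreement on planted instances up to 2 kb.

## Spliced mapping and junction refinement

Exon/intron structure comes from chaining per-exon local hits of a
transcript against its genomic locus (maximum matched bases, colinear and
strand-consistent), absorbing genomic gaps shorter than 20 bp into a
single exon, and rejecting models with more than 30 bp of unaligned
transcript.  Two practical subtleties dominate the accuracy of the
result:

* A local aligner keeps any net-positive alignment tail, so an exon hit
  often extends a few bases — occasionally tens of bases, with small
  gaps — past its true junction into the intron.  Chained neighbours may
  therefore overlap on the transcript; overlaps up to twice the seed
  window padding are tolerated and then resolved explicitly.
* The junction itself is re-derived from *solid anchors*: each side's
  nearest gapless block that is long (≥ 15 columns) and nearly all
  matches.  A single boundary is chosen on the straight diagonals
  projected from those anchors, maximising the joint ±1 match score.
  When the intron bases adjacent to a junction differ from the exon
  continuation — the recognisable boundary that real splice sites
  (GT..AG) provide — this optimum is unique and equals the true
  junction.  When they do not, no aligner can place the boundary from
  sequence alone; the choice is then the deterministic score optimum.
  A refined junction flanked by random-level identity on either side
  means the chain bridged a genuine hole, and the model is rejected
  rather than fabricated.

Because the genome is most informative about its own taxon, the gene
model is inferred from the cluster member whose genomic mapping carries
the most matched bases (typically the conspecific transcript), and that
member becomes the emitted target sequence, so bait coordinates always
refer to a sequence the model actually describes.  Copy number is
likewise assessed with every cluster member: a duplicate locus at, say,
10% divergence from the genome's taxon can sit below the 75% floor for a
distant member yet is plainly visible to the conspecific one, so any
member seeing two qualifying loci (chained identity ≥ 0.75, query
coverage ≥ 0.5, loci separated by more than 10 kb) makes the cluster
multi-copy.

## Selection under the bait budget

Exons shorter than a bait (120 bp) are never targeted but do not
disqualify their marker — the alternative (discarding any marker with a
short exon) throws away otherwise optimal intron-rich markers.  Baits
tile each targetable exon at offsets of `bait_len / coverage` (30 bp at
the defaults) with the final bait right-aligned, so every targetable base
is covered at least once.  Ranking by predicted exon-plus-intron length
adds `n_introns x mean(intron length)` to the exon total; the *global*
pooled mean is used rather than each marker's own intron lengths so that
markers with unusually large introns — which may capture poorly, or be
smaller in the focal clade — are not favoured (a per-marker mean is
available via `mean_intron_scope`).  Selection is greedy first-fit
decreasing: sort by score, add whatever fits the remaining budget.  This
matches the "longest sequences that could be captured" phrasing of the
workflow it implements, is deterministic, and on small instances sits
within 10% of the exhaustive-search optimum in the test suite's
benchmark; an exact knapsack would buy little and lose transparency.

Two footprint quantities are reported.  `capture_footprint` is total
bait length divided by tiling coverage — the conventional arithmetic
(5,770 x 120 / 4 = 173,100 bp at the defaults).  `targeted_len` is the
cumulative length of targetable exons actually covered; right-alignment
of final baits makes it differ from the former by at most one bait
length per exon.

## The synthetic-data generator

`simulate_genome_and_transcriptomes()` builds the validation conditions:
20 gene families over 3 taxa, exons of 250–600 bp (2–5 per gene), introns
of 150–1,000 bp, per-branch divergence drawn from 0.05–0.20 so realised
pairwise identities straddle the 0.75 floor, 25% of families duplicated
in the genome at 0.10 divergence, and 20% private genes.  Families whose
*expected* pairwise identity would land within [0.71, 0.79] are redrawn:
a family statistically at the floor has its cluster membership decided by
single-substitution sampling noise, so both including and excluding it
are "correct" and recovery against a truth table is not meaningful there;
straddling the floor means families on both sides of it.  Divergence is
substitution-only and applied per branch from a common ancestor, so every
planted identity can be recomputed exactly; the truth table records the
realised (not nominal) minimum pairwise identity, under the same
global-alignment definition the similarity filter uses.  The genome
carries taxon 1's copy of each gene, introns included, on a random
strand; paralog duplicates are dispersed (placed at least one
locus-merge gap away from the primary locus — a tandem duplication
closer than that would deliberately count as a single locus and is a
known limitation, not a planted condition).  Intron terminal bases are
drawn to differ from the adjacent exon continuation, the analogue of
recognisable splice boundaries, without which exact junction recovery is
ill-posed for any aligner.

`simulate_capture_contigs()` emulates captured assemblies: per sample
and target, a haplotype at 1% divergence from the target, optionally a
second allele with `k` differences planted inside a single 40 bp window
clear of fragment boundaries, fragments of 300–500 bp overlapping by
80 bp (shared breakpoints and shared flanking sequence across alleles,
since flanks are genomic context), coverage gaps at a configurable rate,
and terminal fragments carrying up to 120 bp of flanking sequence.
Clustering the allele differences keeps the merge phenomenology
well-defined: one difference yields one merged sequence with one IUPAC
ambiguity; two or more yield at least two sequences.  Differences
scattered widely would be separated by fragmentation into single-base
conflicts and silently collapsed — by this pipeline and by the procedure
it models alike.

What the generator does *not* emulate: indels and alignment uncertainty,
rate heterogeneity and codon structure, assembly errors and chimeras,
uneven coverage within a fragment, and polyploid genomes.  Passing the
recovery tests therefore shows the decision logic is implemented
correctly under clean conditions, not that real data will be this
well-behaved.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF/TSV reports are
  1-based inclusive.
* Alignment ties are broken deterministically (smallest query start,
  then subject start); cluster ids, marker order, greedy order and the
  contig merge schedule (longest overlap first, then leftmost) are all
  deterministic, so every result is order-independent and reproducible.
* The intron-aware ranking mode with no introns anywhere degenerates to
  plain exon-length ranking rather than failing; `mean_intron_length()`
  itself refuses an intron-free pool.
* Contigs merge when overlapping at least 30 bp with at most one
  conflicting column, where columns are compared as IUPAC base *sets*;
  the ambiguity written is the union of observed bases, accumulated
  across successive merges.  A column is variable when the intersection
  of the row base-sets is empty, so `{A, R}` is reconcilable and not
  variable.
* Merged sequences less than 90% identical to each other are segregated
  into separate copy groups (putative paralogs); the threshold is
  configuration-exposed and not derived from the original study.
* Problem sizes in the test suite (20-gene fixtures, 200 alignment
  instances, 500 random selection instances) are chosen to exercise
  every decision path at desk scale while keeping a full run in minutes.

## Known limitations

* Protein-space search is not implemented; the catalogue route compares
  nucleotides at a relaxed 0.70 floor, which is blunter than the
  BLASTx-style comparison it replaces for distant references.
* Tandem duplicates within `locus_merge_gap` (10 kb) of each other count
  as one locus and will pass the single-copy filter.
* Isoforms are not collapsed; two isoforms of one gene in one
  transcriptome will flag the cluster multi-copy via the intra-source
  duplicate rule, which is conservative.
* The coordinate-stacked alignment used for synthetic variability
  assumes no indels; empirical alignments should come from a real
  multiple-sequence aligner and can be fed to `variability()` directly.
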