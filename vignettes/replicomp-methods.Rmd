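---
title: "Methods: comparative analysis of multipartite bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of multipartite bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicomp)
```

## Scope

Many environmental bacteria carry multipartite genomes: one ancestral
chromosome plus secondary chromosomes and megaplasmids, each with its own
replication machinery and its own evolutionary history. The model organism
motivating this package is the metal-resistant beta-proteobacterium
*Cupriavidus metallidurans* CH34, whose genome comprises two large circular
chromosomes (CHR1, CHR2) and two megaplasmids (pMOL28, pMOL30). `replicomp`
implements the standard desk-scale computations used to characterize and
compare such replicons:

* windowed GC content and GC skew with replication origin/terminus (ori/ter)
  prediction, optionally refined by DnaA-box clusters;
* degenerate consensus motif scanning on circular DNA with a mismatch budget
  (DnaA boxes, RepA repeats);
* reciprocal-best-hit (RBH) orthology from Smith-Waterman protein alignment,
  ortholog groups, Venn partitions of core/accessory gene content, and
  synteny block (synton) detection;
* replicon distance matrices from ortholog counts with single-linkage
  clustering and Newick export;
* within-genome paralog families via symmetrified transitive closure of an
  all-vs-all similarity graph, with low-complexity masking and multi-domain
  exclusion;
* annotation summary tables (per-replicon CDS categories, normalized COG
  class ratios, mobile-element tallies).

A synthetic-data generator plants every signal these stages detect, so the
whole pipeline is testable end to end with exact ground truth and without
any downloads.

## GC skew and ori/ter prediction

On most bacterial chromosomes the leading strand is enriched in G over C,
so the windowed skew $S_w = (G - C)/(G + C)$ switches sign at the origin
and the terminus. `gc_skew_windows()` uses non-overlapping 2 kb windows by
default, the usual display convention for genome atlases; window and step
are configurable. `N` bases are excluded from both numerator and
denominator; a window with no G or C emits 0 with a warning.

`predict_ori_ter()` works on the per-base cumulative skew
$c_i = \sum_{j \le i} (\pm 1)$ (+1 for G, -1 for C). Because the deposited
start coordinate of a circular sequence is arbitrary, the curve is
detrended by subtracting its linear trend over one full circle; the
detrended curve is rotation-equivariant, so calls shift exactly with
sequence rotation. Under the G-rich-leading-strand convention the origin is
the curve minimum and the terminus the maximum; a flag flips the sign
convention. Numerical choices:

* **No-confidence floor.** A driftless $\pm 1$ random walk of length $L$
  has range of order $\sqrt{L}$; a detrended range below $2\sqrt{L}$ is
  treated as "no confident call" (flagged, not an error).
* **Box refinement.** If a cluster of at least 3 DnaA boxes lies within
  20 kb of the skew minimum, the origin snaps to the cluster midpoint
  (`refined_by_boxes = TRUE`). On real chromosomes the skew transition and
  the DnaA-box cluster can disagree by tens of kilobases; the call reports
  both rather than adjudicating, and the unrefined call is always
  recoverable by omitting `box_clusters`.

## Motif scanning

Consensus motifs accept plain bases, parenthesized alternation
(`"(A/T)"`), and IUPAC codes; the two built-ins are the 9-bp DnaA box
`TTATCCACA` (conventional budget: two mismatches) and the 17-nt RepA repeat
`CGCAGAA(A/T)(C/T)(A/G)GGTACG(C/T)` (scanned exactly; its four two-way
positions give 16 expansions). Matching a degenerate position costs 0
mismatches — the mismatch count is against the consensus, fixed positions
only. `N` in the subject never matches (conservative on ambiguous
sequence). Scans cover both strands (minus-strand hits are matches of the
reverse-complemented motif reported in forward coordinates), wrap across
the origin of circular replicons, and report all overlapping hits without
greedy suppression. `cluster_hits()` groups hits by single-linkage on start
coordinates with a gap ceiling, merging across the origin when the
replicon length is supplied.

## Alignment and orthology

Protein comparison uses an affine-gap Smith-Waterman implemented in C++
(BLOSUM62, gap open 11, extend 1 — classic protein-BLAST parameters; a gap
of length $k$ costs $11 + k$). Traceback ties break deterministically
(diagonal > up > left), and the best cell with the smallest coordinates is
chosen, so alignments are reproducible. Percent identity is computed over
aligned residue-residue columns (gap columns excluded, the BLAST
convention); `coverage_smaller` is the fraction of the shorter protein
spanned by the alignment.

All-vs-all search uses a k-mer prefilter (k = 4, at least 2 shared
distinct k-mers) for speed; `min_shared_kmers = 0` disables it and is the
exhaustive reference mode used by the test oracles. With the filter on,
the best hit is by definition the best *among candidates passing the
filter*; for genuine homologs this coincides with the global best, for
unrelated queries it may not — an accepted trade-off, since downstream
thresholds discard such weak hits anyway. Score ties break to the
lexicographically smaller subject id.

Two proteins in different species are called orthologs when (i) percent
identity is at least 35, (ii) they are reciprocal best hits, and (iii) the
alignment covers at least 80% of the smaller protein. Criterion (iii) is
implemented as a coverage requirement rather than a second identity
computation. On substitution-only synthetic data the planted pairs align
essentially full length; the realized coverage is 0.97-1.0 rather than
exactly 1.0 because a maximal-scoring local alignment trims terminal
mismatching residues.

Ortholog groups are connected components of the pooled RBH graph (single
linkage); the Venn partition counts, for every species subset, the groups
whose species set equals the subset, and separately the proteins they
contain — published gene-content diagrams do not always state which of the
two is displayed, so both are emitted. Single-species regions count
proteins in no multi-species group.

Syntons are maximal runs of ortholog pairs whose gene-order indices are
co-monotone (same or inverted) on both replicons, allowing a configurable
number of intervening unmatched genes (default 1) between consecutive
pairs; runs shorter than the minimal synton size (default 3 genes) are
discarded.

## Replicon clustering

The distance between two replicons is
$d = 1 - n_{\text{orthologs}} / \min(n_A, n_B)$ where $n_A, n_B$ are
protein counts — "size of the smallest genome" is read in protein units
because the numerator is a protein count. Identical proteomes are at 0,
proteomes sharing nothing at 1, and adding a shared ortholog never
increases $d$.

Single-linkage agglomeration is implemented directly (not via
`stats::hclust`) so that ties break deterministically by the
lexicographically smallest pair of cluster labels, a property `hclust`
does not guarantee; `hclust` serves as an independent cross-check in the
test suite. Merge heights are non-decreasing (a single-linkage guarantee),
and the Newick export is ultrametric with leaf depth equal to half the
merge height, so cophenetic distances reproduce merge heights exactly.

For protein-level comparisons (e.g. sigma-factor sets across strains) the
distance is $100 - \text{similarity}$. Similarity is measured over the
whole protein: identical aligned residues (or BLOSUM-positive pairs, via
`mode = "positive"`) as a percentage of the smaller protein's length. We
deliberately do not use identity over aligned columns here: a local
alignment of two *unrelated* 200-residue proteins typically finds a short
segment at 45-55% identity, which would place unrelated proteins at
distance ~50 instead of near 100. Normalizing by protein length restores
the intended behavior (identical = 0, unrelated > 60, typically > 85)
while agreeing with column identity for full-length homologs.

## Paralog families

Within one proteome, families are built in four steps. (1) Low-complexity
masking: sliding 12-residue windows whose Shannon entropy falls below 2.2
bits are replaced by `X` runs (a uniform random 12-mer has ~3.4 bits, a
homopolymer 0). Entropy is computed over non-`X` residues, windows more
than half masked are skipped, and masking iterates to a fixed point —
making it idempotent and preventing mask avalanches at run boundaries.
This windowed-entropy filter is a simplification of the compositional-bias
filters used in published pipelines. (2) An all-vs-all similarity graph
with a directed edge for every hit at >= 30% identity and >= 0.5 coverage
of the smaller protein — a deliberate, configurable proxy for the E-value
cutoffs of BLAST-based pipelines, since no E-value statistics are
implemented. (3) Multi-domain exclusion: a protein is flagged when two of
its neighbors hit spans of it overlapping by less than 20% of the shorter
span *and* those neighbors are not themselves connected — the signature of
a domain fusion, which would otherwise glue unrelated families together
under transitive closure. The 20% cutoff separates clean fusions from
sliding alignments; published accounts give no number. (4)
Symmetrification and closure: asymmetric edges are re-checked with a fresh
full alignment of the missing direction and dropped if it fails the
thresholds; families are the connected components with at least two
members. Families, singletons and excluded proteins always partition the
proteome.

`family_stats()` reports counts and percentages (rounded half-up to
integers) with the analyzed proteome — families plus singletons, excluding
multi-domain proteins — as the documented denominator.

## Annotation summaries

`summarize_annotation()` aggregates per-gene annotation rows (CDS with one
of three categories: assigned / conserved hypothetical / hypothetical,
plus RNA genes and mobile elements) into per-replicon counts, totals and
percentages (one decimal, round-half-up). For transcriptions of published
per-replicon tables — where the three categories need not exhaust the CDS
total — `genome_summary_from_counts()` consumes the counts directly. The
package ships transcriptions for the four CH34 replicons
(`ch34_genome_table()`, `ch34_mobile_elements()`).

The normalized COG ratio between two replicons is
$(n_2/N_2)/(n_1/N_1)$ per functional class: 1 means the class is evenly
distributed once total gene counts are accounted for, values above 1 mean
enrichment on the second (conventionally smaller) replicon. Published
figures do not state whether $N$ is all CDSs or COG-assigned CDSs, nor the
ratio direction; the denominator defaults to COG-assigned CDSs with a
`"cds"` switch, and direction follows the argument order.

## The synthetic-data generator

`simulate_replicon()` draws i.i.d. bases with replichore-specific G/C
probabilities: on the clockwise arc ori -> ter each base is G with
probability $gc/2 + \delta/2$ and C with probability $gc/2 - \delta/2$,
mirrored on the other replichore; planted motif instances (exact mismatch
counts, either strand) overwrite the background. `simulate_proteomes()`
draws ancestral proteins i.i.d. uniform over the 20 residues (length
normal, mean 250, sd 50, truncated at 50 — typical bacterial protein
scale) and derives species copies by substitution-only divergence:
pairwise-disjoint substitution sets make every cross-species identity
exact, which requires identity $\ge 100 - 200/n$ for $n$ species. Paralog
families use the same scheme when the family is small enough and fall back
to independent position draws for large families (realized pairwise
identity slightly above target). Accessory genes are species-private
random sequences; gene order is ancestral with a configurable conserved
fraction.

What this emulates — and what it does not: the generator reproduces the
*signals* (skew switch, motif boxes, orthology at controlled identity,
duplication-divergence families, core/accessory structure; the default
core fraction 0.62 mirrors the share of main-chromosome genes conserved
across the four sequenced *Cupriavidus* strains) but not codon structure,
indels (an explicit design choice so identity and coverage are analytically
controllable), rearrangements, IS-element dynamics, or compositionally
realistic proteins. Passing tests therefore demonstrate algorithmic
correctness against planted truth, not performance on real genomes; the
optional script `inst/scripts/fetch_ch34.R` (network required) runs the
skew/DnaA-box analysis on the deposited CH34 replicons.

All randomness is seeded: simulation specs carry explicit seeds, and
per-component seeds derive from a master seed by fixed offsets, so
identical specs give byte-identical FASTA and truth tables.

## Problem sizes and test design

The test suite and the acceptance script run every stage at desk scale:
10 kb scans against an exhaustive position-by-position oracle, alignment
scores against both an independent dynamic-programming implementation
(`Biostrings::pairwiseAlignment`) and a literal all-substring-pairs brute
force at short lengths, ori/ter recovery on 100 kb replicons over many
seeds (2 kb tolerance), RBH recovery on 4 species x 150 genes planted at
60% identity (recall and accessory false pairs), single-linkage heights
against a naive $O(n^3)$ oracle on random 8x8 matrices, and paralog-family
recovery at Rand index 1.0 against planted truth over repeated seeds.
These sizes were chosen so each property is checked in seconds to a few
minutes while remaining large enough to exercise circular wrap-around,
prefilter behavior and tie-breaking.

## Known limitations

* No E-value statistics: similarity thresholds are identity/coverage
  proxies and are not calibrated to database size.
* Substitution-only synthetic divergence; indel robustness of the
  coverage criterion is not exercised by the planted truth.
* The multi-domain heuristic sees only pairwise alignment spans; it will
  miss fusions whose partners happen to be connected to each other, and
  the 20% overlap cutoff is a design constant, not a fitted value.
* Synton detection is a greedy maximal-chain scan, adequate for the
  conserved-block sizes it is used at; it does not solve the general
  maximum-chaining problem.
* Average/complete linkage are not provided; the clustering module is
  deliberately single-linkage only, matching its intended use.
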