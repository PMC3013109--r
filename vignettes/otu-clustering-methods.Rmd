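---
title: "Methods: robust OTU analysis of 16S rRNA tag data with OTUclust"
author: "OTUclust maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust OTU analysis of 16S rRNA tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OTUclust)
```

## The problem

Amplicon surveys of microbial communities sequence a hypervariable region
of the 16S rRNA gene (for example V3) from thousands of organisms at once,
and summarize the community as operational taxonomic units (OTUs):
equivalence classes of reads within a stated sequence distance, standing in
for species-like units.  Two computational stages dominate the quality of
the result — the multiple alignment of the reads, and the clustering of the
pairwise distances derived from that alignment — and small errors in either
stage inflate OTU counts dramatically.  OTUclust implements that pipeline:
read quality control, alignment merging and hand-curation support, gap-aware
distance computation, deterministic linkage clustering with distance
cutoffs, and quantitative metrics for judging a clustering.

## Quality control and trimming

Reads shorter than `minLen` bp (default 100, measured on the degapped
sequence) are removed first, then reads containing an unknown nucleotide
`N`.  Running the short filter first gives every removed read exactly one
removal cause, so the `QCReport` counts reconcile exactly:
`nInput == nOutput + nRemovedShort + nRemovedAmbiguous`.

Alignments of length-variable reads have ragged, uninformative overhangs.
`classifyColumns()` flags a column as *conserved* when its non-gap
occupancy reaches the `occupancy` threshold (default 0.95) **and** the
modal residue frequency among its non-gap characters reaches the
`identity` threshold (default 0.90); `trimToConserved()` then keeps the
span from the first to the last conserved column.  "Strongly conserved" is
a judgement call in practice; the dual-threshold rule is a reproducible,
tunable stand-in for it.  Comparisons are case-insensitive and U is folded
to T throughout, since rRNA data mixes RNA and DNA alphabets.

## Alignment merging and snippet curation

Covariance-model aligners columnize the strongly structured parts of the
molecule against a secondary-structure template and leave the
hypervariable region unaligned, marked with the Stockholm insert
convention (lowercase residues, `.` gaps).  Template-based aligners
(NAST-style) columnize everything, including the hypervariable region, but
are less faithful in the structured parts.  `mergeAlignments()` combines
the two: structural columns come verbatim from the structure-aware
alignment, while the residues inside each hypervariable block are
re-columnized exactly as in the minimal template-alignment column window
that contains them, with per-sequence residue-to-column maps serving as
the coordinate bridge.  Degapped read content is preserved by
construction; the output is uppercased plain gapped FASTA.

For hand curation, `spliceCut()` cuts the (typically widest) hypervariable
span out of the alignment and dereplicates the degapped in-span snippets —
on real tag datasets this reduces tens of thousands of reads to a few
hundred unique snippets of 1–30 bp.  After curation, `spliceMerge()`
splices the curated snippet alignment back between the untouched flanks.
Dereplication uses the exact degapped string (uppercase, U→T) as its key;
a consequence is that the cut/splice round trip restores every record's
degapped content and all columns outside the span exactly, while the
in-span columnization is canonicalized to each snippet class's
representative.  Two reads that gap the same snippet differently are
deliberately given one shared columnization — that is the point of
dereplication.

## Distances

`psiDistance()` implements percent sequence difference (PSI): count the
columns at which two aligned sequences differ, **a gap opposite a residue
counting as a letter**, and divide by the average of the two ungapped
lengths.  Columns gapped in both sequences are skipped: a shared gap
carries no pairwise signal.  Terminal gaps are treated like internal gaps;
after trimming to the conserved span this choice is low-impact, but it is
stated here for reproducibility.  Note that the average-length denominator
means PSI can violate the triangle inequality; it is a dissimilarity, not
a metric, and nothing downstream assumes otherwise.  Distances are not
binned to two decimals before clustering — exact arithmetic is the
default, and binning compatibility with other tools is left to the caller.

`patristicMatrix()` computes tree distances (sums of branch lengths along
the path between two leaves) from any Newick-backed `phylo` object, by
path summation over the edge table; it is cross-checked in the test suite
against an independent cophenetic implementation and against the
four-point condition on random additive trees.

Matrices are exchanged as Phylip square files or as sparse
`"idA idB distance"` column files, where an unlisted pair means "distance
above the cutoff".

## Clustering

`linkageCluster()` is a deterministic agglomerative clusterer: repeatedly
merge the two clusters with the smallest linkage distance — complete
linkage takes the maximum inter-cluster pair, single the minimum, average
the unweighted mean over all inter-cluster pairs — while that distance
stays within the largest requested cutoff.  Cutting the recorded merge
trace at each cutoff yields the whole cutoff series (3%, 5%, 7%, ...)
from one run.  For complete linkage the cutoff bounds the cluster
*diameter*: every intra-cluster pair is within the cutoff (the package
asserts this invariant on every run).  For sparse, cutoff-limited matrices
an absent pair is treated as larger than any cutoff: it blocks merging
under complete linkage and poisons the average-linkage mean ("unknown
propagates"); single linkage can still chain through known pairs.

Ties among equal minimal linkage distances are broken by the
lexicographically smallest member id of the candidate cluster pairs (then
the second member), using locale-independent byte order.  This makes the
merge sequence fully deterministic and lets the test suite demand *exact*
equivalence with a naive cubic re-implementation of the same rule.  The
production path maintains nearest-neighbour arrays with Lance–Williams
updates (for average linkage the state holds exact pair-distance sums, so
on-demand means are bit-identical to direct means whenever summation is
exact), giving near-quadratic behaviour in practice with quadratic
memory; the suite checks the empirical growth curve on dense random
matrices of 500–2000 items rather than wall-clock times.

`greedyCluster()` implements the heuristic used by greedy tag clusterers:
take a seed, absorb everything within radius `r` of it, repeat.  Members
are within `r` of the seed but may be up to `2r` from each other, so a
radius-`r` greedy clustering is comparable to a diameter-`2r` linkage
clustering (1.5% greedy vs 3% complete linkage).  The default seed order
is the input order; `order = "random"` with a seed reproduces the
randomized variant reproducibly.

## Clustering quality metrics

**Calinski–Harabasz index.**  Sequence space has no coordinates, so the
classic variance-ratio index is generalized to pure distance data: total
dispersion $T = \frac1N \sum_{i<j} d^2_{ij}$, within dispersion
$W = \sum_c \frac{1}{n_c}\sum_{i<j \in c} d^2_{ij}$, between dispersion
$B = T - W$, and
$$\mathrm{CH} = \frac{B/(k-1)}{W/(N-k)}.$$
When $d$ is Euclidean this equals the coordinate formula exactly (pairwise
squared distances collapse to centroid sums of squares), which is the
correctness anchor used in the tests.  $W = 0$ — clusters of mutually
identical sequences, common in duplicate-heavy tag data — returns an
`Inf` sentinel rather than an error.  Because published CH values for
real datasets depend on the (unpublished) exact sequence-space adaptation
used to compute them, magnitudes from this implementation are comparable
within OTUclust analyses, not across tools.

**Uniform clades.**  `uniformCladeCount()` counts internal tree nodes all
of whose leaves carry one OTU label.  The default `maximal` mode counts
only uniform nodes whose parent is not uniform, so a three-leaf uniform
clade contributes one clade, not also its nested uniform cherry; `all`
counts every uniform node.  A good clustering agrees with the phylogeny
and yields many uniform clades.

**Rank abundance.**  `rankAbundance()` sorts OTU sizes descending (ties
ordered by smallest member id, for determinism).
`rescaleRankAbundance()` maps a K-OTU curve onto a target K\* axis by
scaling ranks by $K^*/K$ and heights by $K/K^*$, then resampling at
integer ranks by integrating the scaled step curve over each target rank
bin.  This rebinning is *exactly* area-preserving and keeps the curve
non-increasing; point-interpolation alternatives lose several percent of
area on coarse curves, which would defeat the purpose of comparing curve
shapes across clustering distances.

## Synthetic data: what it emulates and what it does not

`plantedPartitionAlignment()` draws K center sequences at pairwise
divergence ≈ `deltaBetween` (independent uniform-replacement changes at
rate $\delta/2$ from a common ancestor), then `nPer` members per center
at divergence ≈ `deltaWithin`.  A fraction `indelRate` (default 0.2,
echoing the indel-heavy error profile of pyrosequencing reads) of each
member's divergence events is realized as a gap character instead of a
substitution; because PSI counts a gap opposite a residue as a letter,
the realized pairwise PSI tracks the requested divergence whatever the
indel share.  The generator re-measures the emitted alignment and
rejects draws (bounded retries on a perturbed stream) until the largest
within-cluster PSI distance is strictly below the smallest
between-cluster distance; under that invariant the planted partition is
*the* complete-linkage answer for any cutoff in the separation window,
which is what makes parameter-recovery tests deterministic rather than
statistical.  Defaults are `nPer = 10`, `length = 200` columns (typical
hypervariable-tag read length), `deltaWithin = 0.01`,
`deltaBetween = 0.20`.

The generator emulates substitution divergence, modest indel noise, and
clean planted structure.  It does **not** emulate homopolymer/flowgram
sequencing error, chimeras, rate heterogeneity across sites, or the
ragged length variation of raw pyrosequencing reads.  Passing tests
therefore demonstrate the correctness of the algorithms under known
ground truth, not the field performance of any laboratory protocol.

`circlePointsMatrix()` reproduces the classic plane fixture: n points on
a unit circle (evenly spaced with a small seeded angular jitter).  Greedy
clustering at radius 1 fragments the set (order-dependently), while
complete linkage with cutoff equal to the observed diameter always finds
one cluster.  `randomLabeledTree()` provides random rooted topologies
with exponential branch lengths (mean 0.1) for the tree-based metrics.

## Numerical and design choices

* **1-based closed column coordinates** everywhere, as native to R and
  the IRanges containers used for block spans; user-facing CLI spans are
  likewise 1-based inclusive.
* **Normalization** for all comparisons: uppercase, U→T, `.`≡`-`;
  output alignments from the merger are uppercased.
* **Tie-breaks**: linkage merges and all orderings (cluster order,
  rank-abundance ties, snippet order) are resolved by radix string order
  of ids, never by hash or locale order.
* **Sparse semantics**: a missing pair is `Inf` in all three linkages.
* **Degenerate inputs**: empty alignments, all-gap pairs (PSI undefined),
  assignments with $k \le 1$ or $k \ge N$ (CH undefined), and spans
  outside the alignment all raise immediate, named errors; `W = 0` in CH
  returns `Inf`.
* **Rejection budget**: the planted-partition generator retries at most
  20 perturbed draws before failing with advice to widen the divergence
  gap.

Problem sizes used in the shipped test suite were chosen to keep every
check at desk scale: oracle-equivalence sweeps use ≥ 100 random matrices
up to N = 100; property loops use 1000 random alignments/trees of
3–16 records; the growth-curve check clusters dense matrices of
N ∈ {500, 1000, 2000}.  The CH-peak property is demonstrated on planted
fixtures with `deltaWithin = 0.04`, `deltaBetween = 0.30`,
`length = 300`: the within-cluster spread must be resolvable at the read
length, because cutting a dendrogram below the resolution of the data
produces clusters of near-duplicate reads whose vanishing within
dispersion inflates CH — the same reason duplicate-heavy real data can
return the `Inf` sentinel.

## Known limitations

* PSI is not a metric; methods that require the triangle inequality
  should not consume these matrices blindly.
* The CH adaptation is pairwise (centroid-free); absolute values are not
  comparable with coordinate-CH values computed by other tools on other
  representations of the same data.
* The merger requires both alignments to agree exactly on degapped
  content per id (after normalization); it repairs nothing.
* The splicer canonicalizes in-span columnization per snippet class (see
  above).
* The Stockholm reader handles sequence lines and ignores annotation; it
  is not a full Stockholm 1.0 implementation.

## A worked run

```{r example, eval = FALSE}
pp <- plantedPartitionAlignment(K = 3, nPer = 10, seed = 1)
dm <- psiMatrix(pp$alignment)
res <- linkageCluster(dm, cutoffs = c(0.03, 0.05, 0.07))
vapply(res$assignments, nOtus, 0L)     # 3 3 3 at all three cutoffs
g <- greedyCluster(dm, radius = 0.025) # over-splits: >= 3 OTUs
chIndex(dm, res$assignments[["0.05"]]) # separation quality of the cut
```
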