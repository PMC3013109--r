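# OTUclust

Robust operational-taxonomic-unit (OTU) analysis for 16S rRNA
hypervariable tag data.

Amplicon surveys summarize a microbial community as OTUs: equivalence
classes of reads within a stated sequence distance (97% similarity ≈ a
3% clustering distance).  OTU counts are notoriously sensitive to the two
computational stages in between raw reads and the final table — multiple
alignment and distance-based clustering.  OTUclust implements that
pipeline with deterministic, testable components:

* **Quality control** — remove reads < 100 bp or containing `N`, classify
  conserved vs hypervariable alignment columns, trim to the conserved
  span (`filterReads`, `classifyColumns`, `trimToConserved`).
* **Alignment merging** — combine a structure-aware alignment (inserts
  left unaligned, Stockholm lowercase/`.` convention) with a
  template-based alignment of the same reads, taking the hypervariable
  columnization from the template (`mergeAlignments`,
  `findHypervariableBlocks`).
* **Snippet curation** — cut the hypervariable span, dereplicate the
  degapped snippets for hand curation, splice the curated snippet
  alignment back (`spliceCut`, `spliceMerge`).
* **Distances** — gap-aware percent sequence difference (PSI): column
  differences with *gap counted as a letter*, divided by the average
  ungapped length of the pair; and patristic (branch-length path)
  distances from Newick trees (`psiDistance`, `psiMatrix`,
  `patristicMatrix`); Phylip square and sparse column matrix formats.
* **Clustering** — deterministic agglomerative linkage clustering
  (complete / single / average) cut at one or more distance cutoffs,
  where the complete-linkage cutoff bounds the cluster *diameter*; and a
  greedy radius clusterer whose cutoff bounds only the member-to-seed
  *radius*, so radius r is comparable to diameter 2r
  (`linkageCluster`, `greedyCluster`; mothur-style list files).
* **Quality metrics** — a distance-based Calinski–Harabasz index

  CH = (B/(k−1)) / (W/(N−k)),  B = T − W,
  T = (1/N)·Σ_{i<j} d²(i,j),  W = Σ_c (1/n_c)·Σ_{i<j∈c} d²(i,j),

  exactly equal to the classic coordinate formula on Euclidean data;
  uniform-clade counts against a phylogeny; singleton statistics; rank
  abundance curves with exactly area-preserving rescaling (`chIndex`,
  `uniformCladeCount`, `singletonStats`, `rankAbundance`,
  `rescaleRankAbundance`).
* **Synthetic data** — planted-partition gapped alignments with a
  verified separation guarantee, circle point-set fixtures, random
  labelled trees (`plantedPartitionAlignment`, `circlePointsMatrix`,
  `randomLabeledTree`).

A thin command-line front end over these functions ships at
`inst/scripts/otu.R` (subcommands `qc`, `merge`, `splice`, `dist`,
`cluster`, `metrics`, `synth`).

## Worked example

```r
library(OTUclust)

# 3 planted clusters of 10 reads, 200 columns, 1% within / 20% between
pp <- plantedPartitionAlignment(K = 3, nPer = 10, seed = 1)
pp$alignment
#> Alignment with 30 records x 200 columns

dm  <- psiMatrix(pp$alignment)
res <- linkageCluster(dm, cutoffs = c(0.03, 0.05, 0.07))
vapply(res$assignments, nOtus, 0L)
#> 0.03 0.05 0.07
#>    3    3    3

abundances(rankAbundance(res$assignments[["0.05"]]))
#> [1] 10 10 10

chIndex(dm, res$assignments[["0.05"]])
#> [1] 2341.545

g <- greedyCluster(dm, radius = 0.025)   # radius 0.025 ~ diameter 0.05
nOtus(g); singletonStats(g)
#> [1] 4
#>       nOtus nSingletons
#>           4           1
```

Complete linkage recovers the three planted OTUs at every cutoff in the
3–7% series, and the 5% cut scores CH ≈ 2342 with a flat 10/10/10 rank
abundance curve.  The greedy radius clusterer at the comparable setting
over-splits into 4 OTUs, one of them a singleton — the characteristic
failure mode the diameter guarantee of complete linkage avoids.

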