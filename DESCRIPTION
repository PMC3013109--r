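Package: OTUclust
Title: Robust OTU Analysis for 16S rRNA Hypervariable Tag Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for operational taxonomic unit (OTU) analysis of 16S
    rRNA amplicon alignments: quality filtering and trimming to the
    conserved span, merging structure-aware and template-based multiple
    alignments of the same reads, cut/dereplicate/splice support for hand
    curation of hypervariable snippets, gap-aware percent-sequence-difference
    (PSI) and patristic distance matrices, deterministic agglomerative
    linkage clustering (complete, single, average) with distance cutoffs and
    a greedy radius clusterer, and clustering quality metrics (a
    distance-based Calinski-Harabasz index, uniform-clade counts against a
    phylogeny, singleton statistics, and area-preserving rank-abundance
    rescaling). A synthetic-data generator provides planted-partition
    alignments, circle point sets and random labelled trees with known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    ape
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
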