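# Generics and accessor methods.  Slots are never touched directly by user
# code; these accessors are the supported surface.

#' @describeIn Alignment Number of records.
#' @param x,object An object of the documented class.
#' @export
setMethod("length", "Alignment", function(x) length(x@seqs))

#' @describeIn Alignment Record ids.
#' @export
setMethod("names", "Alignment", function(x) names(x@seqs))

#' @describeIn Alignment Gapped sequences as a named character vector.
#' @export
setMethod("as.character", "Alignment", function(x) x@seqs)

#' @describeIn Alignment Subset records by index, id or logical mask; the
#'   column width is unchanged.
#' @param i Record selector.
#' @param j,drop,... Ignored (records are the only dimension).
#' @export
setMethod("[", "Alignment", function(x, i, j, ..., drop = FALSE) {
  Alignment(x@seqs[i])
})

#' Alignment column width
#'
#' @param x An [Alignment-class].
#' @return Integer column count (0 for an empty alignment).
#' @export
alignmentWidth <- function(x) {
  stopifnot(is(x, "Alignment"))
  if (length(x@seqs) == 0L) 0L else nchar(x@seqs[[1L]])
}

#' Sequence ids of an object
#'
#' @param x An [Alignment-class] or [DistanceMatrix-class].
#' @return Character vector of ids.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname seqIds
#' @export
setMethod("seqIds", "Alignment", function(x) names(x@seqs))

#' @rdname seqIds
#' @export
setMethod("seqIds", "DistanceMatrix", function(x) x@ids)

#' @describeIn DistanceMatrix Dense numeric matrix view (NA for omitted
#'   pairs of a sparse matrix).
#' @param x,object A [DistanceMatrix-class].
#' @param ... Ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Is a distance matrix sparse (cutoff-limited)?
#'
#' @param x A [DistanceMatrix-class].
#' @return Logical.
#' @export
isSparse <- function(x) {
  stopifnot(is(x, "DistanceMatrix"))
  !is.na(x@sparseCutoff)
}

#' Number of OTUs in an assignment
#'
#' @param x An [OTUAssignment-class].
#' @return Integer cluster count.
#' @export
nOtus <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  length(x@clusters)
}

#' OTU member lists
#'
#' @param x An [OTUAssignment-class].
#' @return List of character vectors of member ids.
#' @export
otuClusters <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  x@clusters
}

#' OTU sizes
#'
#' @param x An [OTUAssignment-class].
#' @return Integer vector of cluster sizes (unsorted, cluster order).
#' @export
clusterSizes <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  lengths(x@clusters)
}

#' Per-sequence OTU labels
#'
#' @param x An [OTUAssignment-class].
#' @return Named integer vector: id -> cluster index.
#' @export
otuLabels <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  ids <- unlist(x@clusters, use.names = FALSE)
  lab <- rep.int(seq_along(x@clusters), lengths(x@clusters))
  names(lab) <- ids
  lab
}

#' Clustering cutoff of an assignment
#'
#' @param x An [OTUAssignment-class].
#' @return Numeric cutoff, with semantics given by [cutoffSemantics()].
#' @export
otuCutoff <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  x@cutoff
}

#' Cutoff semantics: diameter or radius
#'
#' For linkage clustering the cutoff bounds the cluster diameter; for greedy
#' radius clustering it bounds the member-to-seed distance, so members of
#' one cluster may be up to twice the cutoff apart.
#'
#' @param x An [OTUAssignment-class].
#' @return \code{"diameter"} or \code{"radius"}.
#' @export
cutoffSemantics <- function(x) {
  stopifnot(is(x, "OTUAssignment"))
  x@semantics
}

#' Conserved-column mask
#'
#' @param x A [ColumnClassification-class].
#' @return Logical vector, one element per column.
#' @export
conservedMask <- function(x) {
  stopifnot(is(x, "ColumnClassification"))
  x@conserved
}

#' Abundance vector of a rank abundance curve
#'
#' @param x A [RankAbundance-class].
#' @return Numeric vector, descending.
#' @export
abundances <- function(x) {
  stopifnot(is(x, "RankAbundance"))
  x@abundance
}

#' Unique snippets of a snippet table
#'
#' @param x A [SnippetTable-class].
#' @return Character vector of unique degapped snippet strings.
#' @export
uniqueSnippets <- function(x) {
  stopifnot(is(x, "SnippetTable"))
  x@snippets
}

#' Snippet membership map
#'
#' @param x A [SnippetTable-class].
#' @return Named integer vector: sequence id -> snippet index.
#' @export
snippetMembership <- function(x) {
  stopifnot(is(x, "SnippetTable"))
  x@membership
}

#' QC report counts
#'
#' @param x A [QCReport-class].
#' @return Named integer vector with elements \code{nInput},
#'   \code{nRemovedShort}, \code{nRemovedAmbiguous}, \code{nOutput}.
#' @export
qcCounts <- function(x) {
  stopifnot(is(x, "QCReport"))
  c(nInput = x@nInput, nRemovedShort = x@nRemovedShort,
    nRemovedAmbiguous = x@nRemovedAmbiguous, nOutput = x@nOutput)
}

#' Merge table of a dendrogram
#'
#' @param x A [Dendrogram-class].
#' @return data.frame with columns \code{a}, \code{b} (representative ids of
#'   the merged clusters) and \code{height}.
#' @export
mergeTable <- function(x) {
  stopifnot(is(x, "Dendrogram"))
  x@merges
}

#' Planted-partition truth labels
#'
#' @param x A [SynthTruth-class].
#' @return Named integer vector: id -> planted cluster.
#' @export
trueLabels <- function(x) {
  stopifnot(is(x, "SynthTruth"))
  x@labels
}

#' Generator parameters of a synthetic truth object
#'
#' @param x A [SynthTruth-class].
#' @return Named list of parameters.
#' @export
truthParams <- function(x) {
  stopifnot(is(x, "SynthTruth"))
  x@params
}
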