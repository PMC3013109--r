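#' @import methods
#' @importFrom IRanges IRanges
#' @importClassesFrom IRanges IRanges
NULL

#' Gapped multiple sequence alignment
#'
#' The central exchange object of the package: an ordered set of uniformly
#' wide gapped sequences over the nucleotide alphabet (case-insensitive;
#' lowercase residues and \code{'.'} gaps mark unaligned insert columns, as
#' in the Stockholm convention).
#'
#' @slot seqs Named character vector of gapped sequences; names are the
#'   unique sequence identifiers, all elements have equal width.
#'
#' @seealso [readAlignment()], [writeAlignment()], [alignmentWidth()]
#' @exportClass Alignment
setClass("Alignment", representation(seqs = "character"))

setValidity("Alignment", function(object) {
  s <- object@seqs
  ids <- names(s)
  if (length(s) > 0L) {
    if (is.null(ids) || any(!nzchar(ids)))
      return("all records must have non-empty ids")
    if (anyDuplicated(ids))
      return(paste0("duplicate record ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    w <- nchar(s)
    if (any(w == 0L)) return("records must be non-empty")
    if (length(unique(w)) != 1L)
      return(paste0("ragged alignment: record '", ids[which(w != w[1L])[1L]],
                    "' has width ", w[w != w[1L]][1L], ", expected ", w[1L]))
  }
  TRUE
})

#' Construct an Alignment
#'
#' @param seqs Named character vector of equal-width gapped sequences.
#' @return An [Alignment-class] object.
#' @export
Alignment <- function(seqs = character(0)) {
  new("Alignment", seqs = seqs)
}

#' Conserved/hypervariable column classification
#'
#' Flags each alignment column as conserved or not under dual thresholds: a
#' column is conserved iff its non-gap occupancy reaches
#' \code{occupancyThreshold} and the modal non-gap residue frequency (among
#' non-gap residues, case-folded, U=T) reaches \code{identityThreshold}.
#'
#' @slot conserved Logical mask, one element per alignment column.
#' @slot occupancyThreshold,identityThreshold Fractions in \[0, 1\].
#' @exportClass ColumnClassification
setClass("ColumnClassification",
         representation(conserved = "logical",
                        occupancyThreshold = "numeric",
                        identityThreshold = "numeric"))

setValidity("ColumnClassification", function(object) {
  if (length(object@occupancyThreshold) != 1L ||
      length(object@identityThreshold) != 1L)
    return("thresholds must be single fractions")
  if (anyNA(object@conserved)) return("conserved mask must not contain NA")
  TRUE
})

#' Quality-control report
#'
#' Per-cause removal tallies from [filterReads()].  The short-read filter is
#' applied before the ambiguity filter, so each removed read is counted under
#' exactly one cause and the counts reconcile exactly.
#'
#' @slot nInput,nRemovedShort,nRemovedAmbiguous,nOutput Integer counts with
#'   \code{nOutput == nInput - nRemovedShort - nRemovedAmbiguous}.
#' @exportClass QCReport
setClass("QCReport",
         representation(nInput = "integer", nRemovedShort = "integer",
                        nRemovedAmbiguous = "integer", nOutput = "integer"))

setValidity("QCReport", function(object) {
  if (object@nOutput != object@nInput - object@nRemovedShort -
      object@nRemovedAmbiguous)
    return("QC counts do not reconcile")
  if (any(c(object@nInput, object@nRemovedShort, object@nRemovedAmbiguous,
            object@nOutput) < 0L))
    return("QC counts must be non-negative")
  TRUE
})

#' Dereplicated hypervariable snippet table
#'
#' Result of cutting a column span out of an alignment and collapsing the
#' degapped in-span strings to unique representatives, for hand curation.
#'
#' @slot snippets Character vector of unique degapped snippet strings
#'   (normalized: uppercase, U folded to T), ordered by decreasing membership
#'   count, ties by string.
#' @slot membership Named integer vector mapping sequence id to an index
#'   into \code{snippets}.
#' @slot span The cut column interval as a single
#'   \code{\link[IRanges]{IRanges}} range (1-based, closed).
#' @exportClass SnippetTable
setClass("SnippetTable",
         representation(snippets = "character", membership = "integer",
                        span = "IRanges"))

setValidity("SnippetTable", function(object) {
  if (anyDuplicated(object@snippets)) return("snippets must be unique")
  if (length(object@membership) > 0L &&
      (is.null(names(object@membership)) ||
       any(object@membership < 1L) ||
       any(object@membership > length(object@snippets))))
    return("membership must be named indices into snippets")
  if (length(object@span) != 1L) return("span must be a single range")
  TRUE
})

#' Symmetric pairwise distance matrix
#'
#' Distances over sequence ids, dense or sparse-with-cutoff.  In sparse
#' matrices, pairs whose distance exceeded the cutoff are stored as
#' \code{NA} and are interpreted downstream as "greater than any cutoff".
#'
#' @slot ids Ordered character vector of sequence identifiers.
#' @slot values Numeric square matrix (dimnames = ids); symmetric,
#'   non-negative, zero diagonal; \code{NA} marks omitted pairs.
#' @slot sparseCutoff Single numeric; \code{NA_real_} for dense matrices,
#'   otherwise the distance above which pairs were omitted.
#'
#' @seealso [psiMatrix()], [patristicMatrix()], [readDistanceMatrix()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
         representation(ids = "character", values = "matrix",
                        sparseCutoff = "numeric"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  n <- length(object@ids)
  if (!all(dim(v) == c(n, n))) return("values must be an n x n matrix")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (n > 0L) {
    if (!identical(rownames(v), object@ids) ||
        !identical(colnames(v), object@ids))
      return("dimnames must equal ids")
    if (any(diag(v) != 0, na.rm = TRUE)) return("diagonal must be zero")
    if (anyNA(diag(v))) return("diagonal must be stored (zero)")
    if (any(v < 0, na.rm = TRUE)) return("distances must be non-negative")
    tv <- t(v)
    same <- (is.na(v) & is.na(tv)) | (!is.na(v) & !is.na(tv) &
                                        abs(v - tv) <= 1e-9)
    if (!all(same)) return("matrix must be symmetric")
    if (length(object@sparseCutoff) != 1L)
      return("sparseCutoff must be a single numeric (NA for dense)")
    if (!is.na(object@sparseCutoff)) {
      if (any(v > object@sparseCutoff + 1e-12, na.rm = TRUE))
        return("stored values exceed the sparse cutoff")
    } else if (anyNA(v)) {
      return("dense matrix must not contain NA")
    }
  }
  TRUE
})

#' Construct a DistanceMatrix
#'
#' @param values Symmetric numeric matrix with dimnames; \code{NA} marks
#'   omitted pairs when \code{sparseCutoff} is given.
#' @param ids Sequence identifiers; defaults to \code{rownames(values)}.
#' @param sparseCutoff Omission cutoff, or \code{NA_real_} for dense.
#' @return A [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(values, ids = rownames(values),
                           sparseCutoff = NA_real_) {
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  new("DistanceMatrix", ids = as.character(ids), values = values,
      sparseCutoff = as.numeric(sparseCutoff))
}

#' OTU assignment (partition at a stated cutoff)
#'
#' A partition of sequence ids into clusters at clustering distance
#' \code{cutoff}.  The \code{semantics} flag records whether the cutoff
#' bounds the cluster \emph{diameter} (linkage clustering) or the
#' member-to-seed \emph{radius} (greedy clustering); a radius-r clustering is
#' comparable to a diameter-2r one.
#'
#' @slot clusters List of non-empty, disjoint character vectors of ids,
#'   jointly covering all assigned ids.
#' @slot cutoff Single numeric clustering distance.
#' @slot semantics \code{"diameter"} or \code{"radius"}.
#' @slot method One of \code{"complete"}, \code{"single"}, \code{"average"},
#'   \code{"greedy"}, \code{"imported"}.
#' @exportClass OTUAssignment
setClass("OTUAssignment",
         representation(clusters = "list", cutoff = "numeric",
                        semantics = "character", method = "character"))

setValidity("OTUAssignment", function(object) {
  cl <- object@clusters
  if (any(lengths(cl) == 0L)) return("clusters must be non-empty")
  ids <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(ids))
    return(paste0("id assigned to more than one OTU: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!object@semantics %in% c("diameter", "radius"))
    return("semantics must be 'diameter' or 'radius'")
  if (!object@method %in% c("complete", "single", "average", "greedy",
                            "imported"))
    return("unknown clustering method")
  if (length(object@cutoff) != 1L || object@cutoff < 0)
    return("cutoff must be a single non-negative numeric")
  TRUE
})

#' Construct an OTUAssignment
#'
#' @param clusters List of character vectors of ids (a partition).
#' @param cutoff Clustering distance at which the partition was formed.
#' @param semantics \code{"diameter"} or \code{"radius"}.
#' @param method Clustering method label.
#' @return An [OTUAssignment-class] object.
#' @export
OTUAssignment <- function(clusters, cutoff, semantics = "diameter",
                          method = "imported") {
  clusters <- lapply(clusters, as.character)
  mins <- vapply(clusters, function(x) sort(x, method = "radix")[1L], "")
  clusters <- clusters[order(mins, method = "radix")]
  new("OTUAssignment", clusters = clusters, cutoff = as.numeric(cutoff),
      semantics = semantics, method = method)
}

#' Merge trace of an agglomerative clustering run
#'
#' The ordered list of merges performed by [linkageCluster()], each recorded
#' as the lexicographically smallest member id of the two merged clusters
#' and the linkage height of the merge.  Cutting the trace at a height
#' reproduces the partition at that cutoff.
#'
#' @slot merges A data.frame with character columns \code{a}, \code{b}
#'   (cluster representatives) and numeric \code{height}, in non-decreasing
#'   height order.
#' @slot ids All item ids that entered the clustering.
#' @exportClass Dendrogram
setClass("Dendrogram",
         representation(merges = "data.frame", ids = "character"))

setValidity("Dendrogram", function(object) {
  m <- object@merges
  if (!all(c("a", "b", "height") %in% names(m)))
    return("merges needs columns a, b, height")
  if (nrow(m) > 1L && any(diff(m$height) < -1e-12))
    return("merge heights must be non-decreasing")
  if (nrow(m) > length(object@ids) - 1L)
    return("more merges than items allow")
  TRUE
})

#' Rank abundance curve
#'
#' OTU sizes sorted in descending order; the implicit x-axis is the rank
#' 1..K.  Rescaled curves carry the rescale metadata and may hold
#' non-integer heights.
#'
#' @slot abundance Numeric vector, non-increasing, positive.
#' @slot rescale Empty list for raw curves; for rescaled curves a list with
#'   \code{kOriginal}, \code{kTarget}, \code{xScale}, \code{yScale}.
#' @exportClass RankAbundance
setClass("RankAbundance",
         representation(abundance = "numeric", rescale = "list"))

setValidity("RankAbundance", function(object) {
  a <- object@abundance
  if (length(a) > 1L && any(diff(a) > 1e-9))
    return("abundances must be sorted descending")
  if (any(a <= 0)) return("abundances must be positive")
  if (length(object@rescale) == 0L && any(a != round(a)))
    return("unrescaled abundances must be integers")
  TRUE
})

#' Ground truth of a synthetic planted-partition alignment
#'
#' @slot labels Named integer vector: sequence id -> planted cluster index.
#' @slot params List of generator parameters (K, nPer, length, deltaWithin,
#'   deltaBetween, indelRate, seed) plus the measured empirical divergences.
#' @exportClass SynthTruth
setClass("SynthTruth",
         representation(labels = "integer", params = "list"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "Alignment", function(object) {
  n <- length(object@seqs)
  w <- if (n) nchar(object@seqs[[1L]]) else 0L
  cat("Alignment with", n, "records x", w, "columns\n")
  if (n) {
    k <- min(n, 5L)
    for (i in seq_len(k)) {
      s <- object@seqs[[i]]
      cat(sprintf("  %-12s %s%s\n", names(object@seqs)[i],
                  substr(s, 1L, 50L), if (w > 50L) "..." else ""))
    }
    if (n > k) cat("  ...", n - k, "more records\n")
  }
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nInput, "reads in;",
      object@nRemovedShort, "removed (short),",
      object@nRemovedAmbiguous, "removed (ambiguous N);",
      object@nOutput, "kept\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  n <- length(object@ids)
  cat("DistanceMatrix over", n, "ids",
      if (!is.na(object@sparseCutoff))
        paste0("(sparse, cutoff ", format(object@sparseCutoff), ", ",
               sum(is.na(object@values[upper.tri(object@values)])),
               " pairs omitted)") else "(dense)", "\n")
})

setMethod("show", "OTUAssignment", function(object) {
  cat("OTUAssignment:", length(object@clusters), "OTUs at",
      object@semantics, "cutoff", format(object@cutoff),
      paste0("(", object@method, " clustering, "),
      sum(lengths(object@clusters)), "sequences)\n")
})

setMethod("show", "SnippetTable", function(object) {
  cat("SnippetTable:", length(object@snippets), "unique snippets from",
      length(object@membership), "sequences; span",
      IRanges::start(object@span), "-", IRanges::end(object@span), "\n")
})

setMethod("show", "RankAbundance", function(object) {
  if (length(object@rescale)) {
    cat("RankAbundance (rescaled to K =", length(object@abundance), ")\n")
  } else {
    cat("RankAbundance:", length(object@abundance), "OTUs,",
        sum(object@abundance), "sequences\n")
  }
})

setMethod("show", "Dendrogram", function(object) {
  cat("Dendrogram:", nrow(object@merges), "merges over",
      length(object@ids), "items",
      if (nrow(object@merges)) paste0("(heights ",
        format(min(object@merges$height)), " .. ",
        format(max(object@merges$height)), ")") else "", "\n")
})

setMethod("show", "SynthTruth", function(object) {
  cat("SynthTruth:", length(object@labels), "sequences in",
      length(unique(object@labels)), "planted clusters\n")
})
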