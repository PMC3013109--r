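# Read quality filtering, conserved-column classification, trimming.

#' Filter reads by degapped length and ambiguous bases
#'
#' Removes reads whose degapped length is below \code{minLen}, then (if
#' \code{dropAmbiguous}) reads containing an unknown nucleotide \code{N}.
#' The short filter runs first so every removed read has a single cause and
#' the report reconciles exactly.
#'
#' @param aln An [Alignment-class] (gaps do not count towards length).
#' @param minLen Minimum degapped length in bp (default 100).
#' @param dropAmbiguous Drop reads containing \code{N}/\code{n} (default
#'   \code{TRUE}).
#' @return A list with elements \code{alignment} (kept records, original
#'   order) and \code{report} (a [QCReport-class]).
#' @export
filterReads <- function(aln, minLen = 100L, dropAmbiguous = TRUE) {
  stopifnot(is(aln, "Alignment"))
  if (minLen < 0L) stop("minLen must be >= 0", call. = FALSE)
  seqs <- aln@seqs
  degapLen <- nchar(.degap(seqs))
  short <- degapLen < minLen
  hasN <- grepl("n", seqs, ignore.case = TRUE)
  ambiguous <- !short & dropAmbiguous & hasN
  keep <- !short & !ambiguous
  report <- new("QCReport",
                nInput = length(seqs),
                nRemovedShort = sum(short),
                nRemovedAmbiguous = sum(ambiguous),
                nOutput = sum(keep))
  list(alignment = Alignment(seqs[keep]), report = report)
}

#' Classify alignment columns as conserved or hypervariable
#'
#' A column is conserved iff its non-gap occupancy is at least
#' \code{occupancy} and the modal residue frequency among its non-gap
#' characters (case-folded, U treated as T) is at least \code{identity}.
#' This gives a reproducible stand-in for the by-eye choice of "strongly
#' conserved" columns bounding the trimming span.
#'
#' @param aln A non-empty [Alignment-class].
#' @param occupancy Minimum non-gap fraction, in \[0, 1\] (default 0.95).
#' @param identity Minimum modal non-gap residue fraction, in \[0, 1\]
#'   (default 0.90).
#' @return A [ColumnClassification-class].
#' @export
classifyColumns <- function(aln, occupancy = 0.95, identity = 0.90) {
  stopifnot(is(aln, "Alignment"))
  if (length(aln) == 0L) stop("alignment is empty", call. = FALSE)
  .assertFraction(occupancy, "occupancy")
  .assertFraction(identity, "identity")
  m <- .normChars(.alnCharMat(aln))
  n <- nrow(m)
  conserved <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) / n < occupancy) return(FALSE)
    if (length(res) == 0L) return(FALSE)
    max(tabulate(factor(res))) / length(res) >= identity
  }, logical(1L))
  new("ColumnClassification", conserved = conserved,
      occupancyThreshold = occupancy, identityThreshold = identity)
}

#' Trim an alignment to its conserved span
#'
#' Keeps the columns from the first through the last conserved column,
#' inclusive, removing the ragged hypervariable overhangs outside the
#' conserved core.
#'
#' @param aln An [Alignment-class].
#' @param cc A [ColumnClassification-class] matching \code{aln}'s width.
#' @return The trimmed [Alignment-class]; record order preserved.
#' @export
trimToConserved <- function(aln, cc) {
  stopifnot(is(aln, "Alignment"), is(cc, "ColumnClassification"))
  mask <- cc@conserved
  if (length(mask) != alignmentWidth(aln))
    stop("classification width (", length(mask),
         ") does not match alignment width (", alignmentWidth(aln), ")",
         call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L)
    stop("no conserved column: nothing to trim to", call. = FALSE)
  Alignment(substr(aln@seqs, min(idx), max(idx)))
}
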