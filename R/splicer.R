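# Hand-curation support: cut the (longest) hypervariable span out of an
# alignment, dereplicate the snippets, and splice a curated snippet
# alignment back between the flanks.

#' Cut a column span out of an alignment and dereplicate the snippets
#'
#' The in-span content of each sequence is degapped and normalized
#' (uppercase, U to T), then collapsed to unique snippet strings.  On tag
#' datasets this reduces tens of thousands of reads to a few hundred short
#' snippets that can be curated by hand.
#'
#' @param aln An [Alignment-class].
#' @param span Single \code{\link[IRanges]{IRanges}} range (1-based,
#'   closed) inside the alignment; typically the widest block from
#'   [findHypervariableBlocks()].
#' @return List with elements \code{leftFlank} and \code{rightFlank}
#'   ([Alignment-class]s keeping the original columns outside the span;
#'   possibly zero-width) and \code{snippets} (a [SnippetTable-class],
#'   snippets ordered by decreasing membership count, ties by string).
#' @export
spliceCut <- function(aln, span) {
  stopifnot(is(aln, "Alignment"))
  if (is.numeric(span) && length(span) == 2L) {
    if (span[1L] > span[2L])
      stop("empty span ", span[1L], "-", span[2L], call. = FALSE)
    span <- IRanges::IRanges(span[1L], span[2L])
  }
  if (length(span) != 1L) stop("span must be a single range", call. = FALSE)
  s <- IRanges::start(span); e <- IRanges::end(span)
  w <- alignmentWidth(aln)
  if (s < 1L || e > w || s > e)
    stop("empty or out-of-range span ", s, "-", e, " for width ", w,
         call. = FALSE)
  ids <- names(aln@seqs)
  snip <- .normDegap(substr(aln@seqs, s, e))
  uniq <- unique(snip)
  counts <- as.integer(table(factor(snip, levels = uniq)))
  ord <- order(-counts, uniq, method = "radix")
  uniq <- uniq[ord]
  membership <- stats::setNames(match(snip, uniq), ids)
  left <- stats::setNames(substr(aln@seqs, 1L, s - 1L), ids)
  right <- stats::setNames(substr(aln@seqs, e + 1L, w), ids)
  tab <- new("SnippetTable", snippets = uniq, membership = membership,
             span = IRanges::IRanges(s, e))
  list(leftFlank = .flankAlignment(left, ids),
       snippets = tab,
       rightFlank = .flankAlignment(right, ids))
}

# A flank may be zero-width; Alignment requires non-empty records, so a
# zero-width flank is represented by an empty-seq sentinel list instead.
.flankAlignment <- function(seqs, ids) {
  if (all(nchar(seqs) == 0L)) {
    structure(list(ids = ids), class = "emptyFlank")
  } else {
    Alignment(stats::setNames(seqs, ids))
  }
}

.flankSeqs <- function(flank, ids) {
  if (inherits(flank, "emptyFlank"))
    stats::setNames(rep("", length(ids)), ids)
  else {
    stopifnot(is(flank, "Alignment"))
    as.character(flank)[ids]
  }
}

#' Splice a curated snippet alignment back between the flanks
#'
#' Each sequence receives the curated gapped row of its snippet class
#' between its left and right flank columns.  The curated rows may widen or
#' narrow the span, but must degap to the original snippet strings.
#'
#' @param leftFlank,rightFlank Flank objects as returned by [spliceCut()].
#' @param curated [Alignment-class] with one gapped row per unique snippet,
#'   in the order of \code{uniqueSnippets(snippets)} (row ids are free, the
#'   order carries the correspondence).
#' @param snippets The [SnippetTable-class] from [spliceCut()].
#' @return The re-assembled [Alignment-class]; every record degaps to its
#'   pre-cut content.
#' @export
spliceMerge <- function(leftFlank, curated, snippets, rightFlank) {
  stopifnot(is(curated, "Alignment"), is(snippets, "SnippetTable"))
  uniq <- snippets@snippets
  if (length(curated) != length(uniq))
    stop("curated alignment has ", length(curated), " rows but ",
         length(uniq), " unique snippets were cut", call. = FALSE)
  rows <- as.character(curated)
  got <- .normDegap(rows)
  bad <- which(got != uniq)
  if (length(bad))
    stop("curated row ", bad[1L], " degaps to '", got[bad[1L]],
         "' but snippet ", bad[1L], " is '", uniq[bad[1L]], "'",
         call. = FALSE)
  ids <- names(snippets@membership)
  mid <- rows[snippets@membership]
  out <- paste0(.flankSeqs(leftFlank, ids), mid, .flankSeqs(rightFlank, ids))
  Alignment(stats::setNames(out, ids))
}

#' Write snippet curation exchange files
#'
#' Emits the unique snippets as FASTA records named
#' \code{snippet_<k>_n<count>} plus a two-column membership TSV
#' (\code{id}, \code{snippet} index).
#'
#' @param snippets A [SnippetTable-class].
#' @param fastaPath,membershipPath Output paths.
#' @return Invisibly, \code{fastaPath}.
#' @export
writeSnippets <- function(snippets, fastaPath, membershipPath) {
  stopifnot(is(snippets, "SnippetTable"))
  counts <- tabulate(snippets@membership, nbins = length(snippets@snippets))
  nm <- sprintf("snippet_%d_n%d", seq_along(snippets@snippets), counts)
  # empty snippets cannot be FASTA records; write a gap placeholder
  seqs <- ifelse(nchar(snippets@snippets) == 0L, "-", snippets@snippets)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, nm)), fastaPath)
  utils::write.table(
    data.frame(id = names(snippets@membership),
               snippet = snippets@membership),
    membershipPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}
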