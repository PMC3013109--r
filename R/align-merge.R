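# Merging a structure-aware alignment (hypervariable residues left
# unaligned as lowercase insert columns) with a template-based alignment of
# the same reads: structural columns are taken from the former, the
# columnization of each hypervariable block from the latter.

#' Map residues to alignment columns
#'
#' For every record, the column index of each non-gap residue, 0-based along
#' the degapped sequence in reading order.  This is the coordinate bridge
#' used to carry residues between two alignments of the same reads.
#'
#' @param aln An [Alignment-class].
#' @return Named list of strictly increasing integer vectors (1-based
#'   columns); an all-gap record yields an empty vector.
#' @export
buildResidueColumnMap <- function(aln) {
  stopifnot(is(aln, "Alignment"))
  lapply(strsplit(aln@seqs, "", fixed = TRUE),
         function(ch) which(!.isGapChar(ch)))
}

#' Locate hypervariable (insert) blocks
#'
#' Covariance-model aligners leave hypervariable regions unaligned, marking
#' them with the Stockholm insert convention: lowercase residues and
#' \code{'.'} gaps.  A column is an insert column iff all its residues are
#' lowercase (an all-gap column counts when its gaps are dots); maximal runs
#' of insert columns are returned as hypervariable blocks.
#'
#' @param aln An [Alignment-class].
#' @return An \code{\link[IRanges]{IRanges}} of hypervariable blocks
#'   (1-based, closed), ordered by start.  If the alignment shows no insert
#'   convention at all (no lowercase, no dot), an empty set is returned with
#'   a warning.
#' @export
findHypervariableBlocks <- function(aln) {
  stopifnot(is(aln, "Alignment"))
  m <- .alnCharMat(aln)
  if (ncol(m) == 0L) return(IRanges::IRanges())
  anyLower <- any(grepl("[a-z]", aln@seqs))
  anyDot <- any(grepl(".", aln@seqs, fixed = TRUE))
  if (!anyLower && !anyDot) {
    warning("no insert convention detected (no lowercase residues, ",
            "no '.' gaps); returning no hypervariable blocks", call. = FALSE)
    return(IRanges::IRanges())
  }
  insert <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[!.isGapChar(col)]
    if (length(res) == 0L) all(col == ".") else all(grepl("[a-z]", res))
  }, logical(1L))
  r <- rle(insert)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

# Partition [1, width] into segments, tagging each as hypervariable or not.
.blockPartition <- function(width, blocks) {
  if (length(blocks) == 0L) {
    return(data.frame(start = 1L, end = width, hyper = FALSE))
  }
  ord <- order(IRanges::start(blocks))
  s <- IRanges::start(blocks)[ord]; e <- IRanges::end(blocks)[ord]
  if (any(s < 1L) || any(e > width) || any(s > e))
    stop("block spans outside alignment columns 1..", width, call. = FALSE)
  if (length(blocks) > 1L && any(s[-1L] <= e[-length(e)]))
    stop("block spans overlap", call. = FALSE)
  segs <- list()
  pos <- 1L
  for (k in seq_along(s)) {
    if (pos < s[k])
      segs[[length(segs) + 1L]] <- c(pos, s[k] - 1L, 0L)
    segs[[length(segs) + 1L]] <- c(s[k], e[k], 1L)
    pos <- e[k] + 1L
  }
  if (pos <= width) segs[[length(segs) + 1L]] <- c(pos, width, 0L)
  out <- do.call(rbind, segs)
  data.frame(start = out[, 1L], end = out[, 2L], hyper = out[, 3L] == 1L)
}

#' Merge two alignments of the same reads
#'
#' Columns outside the hypervariable blocks are taken verbatim from
#' \code{structureAln}.  Inside each block, the residues falling in the
#' block are re-columnized exactly as in the minimal \code{templateAln}
#' column window containing those residues across all sequences; sequences
#' with no residue in a block receive all-gap columns there.  Degapped
#' content of every record is unchanged (up to uppercasing); output width
#' may differ from either input.
#'
#' @param structureAln Structure-aware [Alignment-class] (e.g. a covariance
#'   model alignment with insert columns).
#' @param templateAln Template-based [Alignment-class] of the same reads
#'   (identical ids and degapped content after case folding and U/T
#'   normalization).
#' @param blocks Hypervariable column spans of \code{structureAln}, as an
#'   \code{\link[IRanges]{IRanges}}; defaults to
#'   [findHypervariableBlocks()] on \code{structureAln}.
#' @param provenance If \code{TRUE}, also return a per-column provenance
#'   mask (\code{"structure"}/\code{"template"}).
#' @return The merged [Alignment-class], uppercased; or, with
#'   \code{provenance = TRUE}, a list with elements \code{alignment} and
#'   \code{provenance}.
#' @export
mergeAlignments <- function(structureAln, templateAln,
                            blocks = findHypervariableBlocks(structureAln),
                            provenance = FALSE) {
  stopifnot(is(structureAln, "Alignment"), is(templateAln, "Alignment"))
  idsS <- names(structureAln@seqs)
  idsT <- names(templateAln@seqs)
  if (!setequal(idsS, idsT)) {
    onlyS <- setdiff(idsS, idsT); onlyT <- setdiff(idsT, idsS)
    stop("id sets differ; only in structure: {",
         paste(onlyS, collapse = ", "), "}; only in template: {",
         paste(onlyT, collapse = ", "), "}", call. = FALSE)
  }
  degS <- .normDegap(structureAln@seqs)
  degT <- .normDegap(templateAln@seqs[idsS])
  bad <- idsS[degS != degT]
  if (length(bad))
    stop("degapped content differs between alignments for id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  widthS <- alignmentWidth(structureAln)
  part <- .blockPartition(widthS, blocks)
  mapS <- buildResidueColumnMap(structureAln)
  mapT <- buildResidueColumnMap(templateAln)
  # residue characters come from the structure record, uppercased
  resChars <- strsplit(toupper(.degap(structureAln@seqs)), "", fixed = TRUE)

  pieces <- vector("list", nrow(part))
  prov <- character(0)
  for (g in seq_len(nrow(part))) {
    s <- part$start[g]; e <- part$end[g]
    if (!part$hyper[g]) {
      pieces[[g]] <- stats::setNames(
        toupper(chartr(".", "-", substr(structureAln@seqs, s, e))), idsS)
      if (provenance) prov <- c(prov, rep("structure", e - s + 1L))
      next
    }
    # in-block residue indices per id (contiguous because maps increase)
    resIdx <- lapply(idsS, function(id) which(mapS[[id]] >= s & mapS[[id]] <= e))
    names(resIdx) <- idsS
    tcols <- lapply(idsS, function(id) mapT[[id]][resIdx[[id]]])
    names(tcols) <- idsS
    allT <- unlist(tcols, use.names = FALSE)
    if (length(allT) == 0L) {         # nobody has residues here: block vanishes
      pieces[[g]] <- stats::setNames(rep("", length(idsS)), idsS)
      next
    }
    w0 <- min(allT); w1 <- max(allT)
    bw <- w1 - w0 + 1L
    pieces[[g]] <- stats::setNames(vapply(idsS, function(id) {
      row <- rep("-", bw)
      if (length(resIdx[[id]]))
        row[tcols[[id]] - w0 + 1L] <- resChars[[id]][resIdx[[id]]]
      paste(row, collapse = "")
    }, ""), idsS)
    if (provenance) prov <- c(prov, rep("template", bw))
  }
  merged <- Alignment(stats::setNames(
    do.call(paste0, pieces), idsS))
  if (provenance) list(alignment = merged, provenance = prov) else merged
}
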