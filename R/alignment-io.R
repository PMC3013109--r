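# Alignment input/output: gapped FASTA (via Biostrings) and Stockholm.

#' Read a gapped multiple alignment
#'
#' FASTA is parsed with \pkg{Biostrings}; sequences are kept verbatim
#' (case and \code{'.'} insert gaps preserved, so the Stockholm lowercase /
#' dot convention survives a FASTA round trip).  Stockholm files are parsed
#' directly, concatenating wrapped blocks per sequence and ignoring
#' \code{#=GF/#=GC/...} annotation lines.
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @return An [Alignment-class].  Ragged inputs raise an error naming the
#'   offending record; an empty file raises \code{"no records"}.
#' @export
readAlignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(ss), names(ss))
    },
    stockholm = .readStockholm(path))
  if (length(seqs) == 0L) stop("no records in '", path, "'", call. = FALSE)
  # first-word ids, as alignment tools emit descriptions after whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Alignment(seqs)
}

# Minimal Stockholm 1.0 parser: sequence lines are "<name> <aligned seq>",
# possibly wrapped over several '//'-free blocks; markup lines start with '#'.
.readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: '", ln, "'", call. = FALSE)
    nm <- parts[[1L]]
    if (nm %in% names(seqs)) {
      seqs[[nm]] <- paste0(seqs[[nm]], parts[[2L]])
    } else {
      seqs[[nm]] <- parts[[2L]]
    }
  }
  seqs
}

#' Write an alignment as gapped FASTA
#'
#' @param aln An [Alignment-class].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(aln, path, width = 70L) {
  stopifnot(is(aln, "Alignment"))
  ss <- Biostrings::BStringSet(aln@seqs)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}
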