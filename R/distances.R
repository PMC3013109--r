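# Pairwise distances: gap-aware percent sequence difference (PSI) on a
# multiple alignment, and patristic distance on a phylogenetic tree.

#' Percent-sequence-difference (PSI) between two aligned sequences
#'
#' Counts the columns in which the two gapped sequences differ, a gap
#' opposite a residue counting as a letter difference, and divides by the
#' average of the two ungapped lengths.  Comparison is case-insensitive, U
#' is treated as T and \code{'.'} as \code{'-'}; columns gapped in both
#' sequences carry no pairwise signal and are skipped.  Note that the
#' average-length denominator can violate the triangle inequality; PSI is a
#' dissimilarity, not a metric.
#'
#' @param a,b Gapped sequence strings of equal width (same alignment).
#' @return A single non-negative numeric.
#' @examples
#' psiDistance("ACGT", "AC-T")  # 1 difference / mean(4, 3) = 2/7
#' @export
psiDistance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) != nchar(b))
    stop("sequences are not from the same alignment (widths ", nchar(a),
         " and ", nchar(b), ")", call. = FALSE)
  ca <- .normChars(strsplit(a, "", fixed = TRUE)[[1L]])
  cb <- .normChars(strsplit(b, "", fixed = TRUE)[[1L]])
  la <- sum(ca != "-"); lb <- sum(cb != "-")
  if (la + lb == 0L)
    stop("both sequences are fully gapped: PSI undefined", call. = FALSE)
  sum(ca != cb) / ((la + lb) / 2)
}

#' PSI distance matrix of an alignment
#'
#' All pairwise [psiDistance()] values; optionally sparse, omitting pairs
#' whose distance exceeds \code{sparseCutoff} (the convention of
#' cutoff-limited distance files consumed by clustering tools).
#'
#' @param aln An [Alignment-class] with at least 2 records.
#' @param sparseCutoff Optional omission cutoff; \code{NULL} for dense.
#' @param precision Optional decimal places to bin distances to before
#'   returning (compatibility with tools that round to 2 decimals);
#'   \code{NULL} (the default) keeps exact arithmetic.
#' @return A [DistanceMatrix-class].
#' @export
psiMatrix <- function(aln, sparseCutoff = NULL, precision = NULL) {
  stopifnot(is(aln, "Alignment"))
  n <- length(aln)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  enc <- .encodeAln(aln)
  ug <- rowSums(enc != 0L)
  ids <- names(aln@seqs)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ei <- enc[i, ]
    for (j in (i + 1L):n) {
      denom <- (ug[i] + ug[j]) / 2
      if (denom == 0)
        stop("both '", ids[i], "' and '", ids[j],
             "' are fully gapped: PSI undefined", call. = FALSE)
      d <- sum(ei != enc[j, ]) / denom
      v[i, j] <- d; v[j, i] <- d
    }
  }
  if (!is.null(precision)) v <- round(v, precision)
  if (!is.null(sparseCutoff)) {
    v[v > sparseCutoff] <- NA_real_
    diag(v) <- 0
    DistanceMatrix(v, ids, sparseCutoff = sparseCutoff)
  } else {
    DistanceMatrix(v, ids)
  }
}

#' Patristic distance matrix from a phylogenetic tree
#'
#' The distance between two leaves is the sum of branch lengths along the
#' unique tree path connecting them, computed by path summation over the
#' tree's edge table.  Edges without a stated length count as length 0.
#'
#' @param tree An \code{\link[ape]{ape}} \code{phylo} object (e.g. from
#'   \code{ape::read.tree} on a Newick file).
#' @param ids Optional subset of leaf labels; default all leaves.
#' @return A dense [DistanceMatrix-class] over the requested leaves.
#' @export
patristicMatrix <- function(tree, ids = NULL) {
  if (!inherits(tree, "phylo"))
    stop("tree must be an ape 'phylo' object", call. = FALSE)
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("leaf labels must be unique", call. = FALSE)
  if (is.null(ids)) ids <- labs
  unknown <- setdiff(ids, labs)
  if (length(unknown))
    stop("unknown leaf id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  nNode <- max(tree$edge)
  parent <- integer(nNode); plen <- numeric(nNode)
  elen <- tree$edge.length
  if (is.null(elen)) elen <- numeric(nrow(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- elen
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  # path from each requested leaf up to the root, with cumulative depths
  paths <- lapply(match(ids, labs), function(tip) {
    nodes <- tip; node <- tip
    while (node != root) { node <- parent[node]; nodes <- c(nodes, node) }
    depth <- c(0, cumsum(plen[nodes[-length(nodes)]]))
    list(nodes = nodes, depth = depth)
  })
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    di <- stats::setNames(paths[[i]]$depth, paths[[i]]$nodes)
    for (j in seq_len(n)) {
      if (j <= i) next
      nj <- paths[[j]]$nodes
      lcaPos <- which(as.character(nj) %in% names(di))[1L]
      lca <- as.character(nj[lcaPos])
      d <- di[[lca]] + paths[[j]]$depth[lcaPos]
      v[i, j] <- d; v[j, i] <- d
    }
  }
  DistanceMatrix(v, ids)
}

#' Read a distance matrix
#'
#' Supports the Phylip square format (header line with N, then one row per
#' id) and the sparse three-column format \code{"idA idB distance"}, where
#' unlisted pairs mean the distance exceeded the cutoff.
#'
#' @param path File path.
#' @param format \code{"phylip_square"} or \code{"column_sparse"}.
#' @param cutoff For \code{column_sparse}: the omission cutoff the file was
#'   written with; defaults to the maximum listed distance.
#' @param ids For \code{column_sparse}: the full id universe, for ids whose
#'   every pair exceeded the cutoff; defaults to the ids seen in the file.
#' @return A [DistanceMatrix-class].  Asymmetric Phylip entries beyond 1e-6
#'   raise an error.
#' @export
readDistanceMatrix <- function(path, format = c("phylip_square",
                                                "column_sparse"),
                               cutoff = NULL, ids = NULL) {
  format <- match.arg(format)
  if (format == "phylip_square") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1L]))
    if (is.na(n) || length(lines) != n + 1L)
      stop("malformed phylip matrix: expected ", n, " rows", call. = FALSE)
    parts <- strsplit(trimws(lines[-1L]), "\\s+")
    rids <- vapply(parts, `[[`, "", 1L)
    v <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
    if (anyNA(v)) stop("non-numeric entry in phylip matrix", call. = FALSE)
    if (max(abs(v - t(v))) > 1e-6)
      stop("phylip matrix asymmetric beyond 1e-6", call. = FALSE)
    v <- (v + t(v)) / 2
    diag(v) <- 0
    DistanceMatrix(v, rids)
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("a", "b", "d"),
                             colClasses = c("character", "character",
                                            "numeric"))
    if (is.null(ids)) ids <- sort(unique(c(tab$a, tab$b)), method = "radix")
    if (is.null(cutoff)) cutoff <- if (nrow(tab)) max(tab$d) else 0
    n <- length(ids)
    v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(v) <- 0
    ia <- match(tab$a, ids); ib <- match(tab$b, ids)
    if (anyNA(ia) || anyNA(ib))
      stop("sparse file names ids outside the given universe", call. = FALSE)
    v[cbind(ia, ib)] <- tab$d
    v[cbind(ib, ia)] <- tab$d
    DistanceMatrix(v, ids, sparseCutoff = cutoff)
  }
}

#' Write a distance matrix
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output path.
#' @param format \code{"phylip_square"} (dense only) or
#'   \code{"column_sparse"} (stored pairs only).
#' @param digits Decimal places written (round-trip stable to 1e-6 at the
#'   default 6).
#' @return Invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(dm, path,
                                format = c("phylip_square", "column_sparse"),
                                digits = 6L) {
  stopifnot(is(dm, "DistanceMatrix"))
  format <- match.arg(format)
  v <- dm@values
  if (format == "phylip_square") {
    if (isSparse(dm))
      stop("phylip square format cannot represent a sparse matrix",
           call. = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(as.character(length(dm@ids)), con)
    for (i in seq_along(dm@ids)) {
      writeLines(paste(dm@ids[i],
                       paste(formatC(v[i, ], format = "f", digits = digits),
                             collapse = " ")), con)
    }
  } else {
    ut <- which(upper.tri(v) & !is.na(v), arr.ind = TRUE)
    lines <- sprintf("%s %s %s", dm@ids[ut[, 1L]], dm@ids[ut[, 2L]],
                     formatC(v[ut], format = "f", digits = digits))
    writeLines(lines, path)
  }
  invisible(path)
}
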