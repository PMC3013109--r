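# OTU clustering: deterministic agglomerative linkage (complete / single /
# average) with distance cutoffs, and a greedy radius clusterer.

#' Agglomerative linkage clustering with distance cutoffs
#'
#' Standard agglomerative clustering: repeatedly merge the pair of clusters
#' with the smallest linkage distance (complete = maximum inter-cluster
#' pair, single = minimum, average = unweighted mean over all inter-cluster
#' pairs), stopping once that distance exceeds the largest cutoff.  Each
#' returned assignment is the dendrogram cut at one cutoff, so a single run
#' yields the whole cutoff series (e.g. 3\%, 5\%, 7\%).  For complete
#' linkage the cutoff bounds the cluster \emph{diameter}: every
#' intra-cluster pair is within the cutoff, which is what makes the method
#' robust against the chaining and over-splitting of greedy heuristics.
#'
#' Sparse matrices are supported: an omitted pair is treated as larger than
#' any cutoff, so it blocks merging under complete linkage and poisons the
#' average linkage mean.
#'
#' Ties among equal minimal linkage distances are broken by the
#' lexicographically smallest member id of the candidate pairs (then the
#' second member), making runs fully deterministic.
#'
#' @param dm A [DistanceMatrix-class].
#' @param cutoffs Numeric vector of non-negative cutoffs, ascending.
#' @param method \code{"complete"} (default), \code{"single"} or
#'   \code{"average"}.
#' @return List with \code{assignments} (a list of [OTUAssignment-class],
#'   one per cutoff, named by cutoff) and \code{dendrogram} (a
#'   [Dendrogram-class] of the merges performed).
#' @examples
#' dm <- circlePointsMatrix(8, seed = 1)
#' res <- linkageCluster(dm, cutoffs = max(as.matrix(dm)))
#' nOtus(res$assignments[[1]])  # 1: cutoff = diameter merges everything
#' @export
linkageCluster <- function(dm, cutoffs,
                           method = c("complete", "single", "average")) {
  stopifnot(is(dm, "DistanceMatrix"))
  method <- match.arg(method)
  ids <- dm@ids
  n <- length(ids)
  if (n == 0L) stop("empty distance matrix", call. = FALSE)
  if (length(cutoffs) == 0L || any(cutoffs < 0))
    stop("cutoffs must be non-negative", call. = FALSE)
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending", call. = FALSE)
  mcode <- match(method, c("complete", "single", "average")) - 1L
  core <- .linkageCore(dm@values, .lexRank(ids), mcode, max(cutoffs))
  merges <- data.frame(a = ids[core$a + 1L], b = ids[core$b + 1L],
                       height = core$height, stringsAsFactors = FALSE)
  dendro <- new("Dendrogram", merges = merges, ids = ids)
  assignments <- lapply(cutoffs, function(cut) {
    cl <- .cutMerges(ids, merges, cut)
    out <- OTUAssignment(cl, cutoff = cut, semantics = "diameter",
                         method = method)
    if (method == "complete") .assertDiameter(dm, out)
    out
  })
  names(assignments) <- format(cutoffs, trim = TRUE)
  list(assignments = assignments, dendrogram = dendro)
}

# Union-find cut of a merge list at a height.
.cutMerges <- function(ids, merges, cutoff) {
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- merges$height <= cutoff
  for (r in which(keep)) {
    ra <- find(match(merges$a[r], ids))
    rb <- find(match(merges$b[r], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(ids), find, 0L)
  unname(lapply(split(ids, roots),
                function(x) sort(x, method = "radix")))
}

# Complete linkage guarantee: every intra-cluster pair with a known
# distance is within the cutoff.  Asserted on every run.
.assertDiameter <- function(dm, assignment) {
  v <- dm@values
  for (cl in assignment@clusters) {
    if (length(cl) < 2L) next
    sub <- v[cl, cl]
    if (any(sub > assignment@cutoff + 1e-12, na.rm = TRUE))
      stop("internal error: complete-linkage diameter guarantee violated",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Greedy radius clustering
#'
#' The heuristic used by greedy tag clusterers: take an unassigned sequence
#' as a seed and absorb every unassigned sequence within \code{radius} of
#' it; repeat until all sequences are assigned.  Members are guaranteed to
#' be within \code{radius} of their seed, but two members of one cluster
#' may be up to \code{2 * radius} apart, so a radius-r greedy clustering is
#' comparable to a diameter-2r linkage clustering.
#'
#' @param dm A dense [DistanceMatrix-class].
#' @param radius Non-negative clustering radius.
#' @param order \code{"input"} (default) processes seeds in matrix id
#'   order; \code{"random"} shuffles the seed order reproducibly.
#' @param seed RNG seed for \code{order = "random"}.
#' @return An [OTUAssignment-class] with \code{semantics = "radius"}; the
#'   first member of each cluster is its seed.
#' @export
greedyCluster <- function(dm, radius, order = c("input", "random"),
                          seed = NULL) {
  stopifnot(is(dm, "DistanceMatrix"))
  order <- match.arg(order)
  if (radius < 0) stop("radius must be non-negative", call. = FALSE)
  if (isSparse(dm))
    stop("greedy clustering needs a dense matrix", call. = FALSE)
  ids <- dm@ids
  ord <- seq_along(ids)
  if (order == "random")
    ord <- .withSeed(seed, sample(ord))
  v <- dm@values
  assigned <- logical(length(ids))
  clusters <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- which(!assigned & v[i, ] <= radius)
    members <- c(i, setdiff(members, i))
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- ids[members]
  }
  new("OTUAssignment", clusters = clusters, cutoff = as.numeric(radius),
      semantics = "radius", method = "greedy")
}

#' Write OTU assignments as a mothur-style list file
#'
#' One line per assignment: the cutoff label, the OTU count, then one
#' tab-separated field per OTU holding its comma-separated member ids.
#'
#' @param assignments An [OTUAssignment-class] or a list of them.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeOtus <- function(assignments, path) {
  if (is(assignments, "OTUAssignment")) assignments <- list(assignments)
  lines <- vapply(assignments, function(a) {
    otus <- vapply(a@clusters, paste, "", collapse = ",")
    paste(c(format(a@cutoff, trim = TRUE), length(otus), otus),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a mothur-style list file
#'
#' @param path File path.
#' @param semantics Cutoff semantics to record (\code{"diameter"} default).
#' @return List of [OTUAssignment-class] (method \code{"imported"}), one
#'   per line.  Malformed lines and duplicate ids raise errors naming the
#'   line.
#' @export
readOtus <- function(path, semantics = "diameter") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", k, ": expected label, count and at least one OTU",
           call. = FALSE)
    cutoff <- suppressWarnings(as.numeric(f[1L]))
    nOtu <- suppressWarnings(as.integer(f[2L]))
    otus <- strsplit(f[-(1:2)], ",", fixed = TRUE)
    if (is.na(nOtu) || length(otus) != nOtu)
      stop("line ", k, ": OTU count field (", f[2L],
           ") does not match the ", length(otus), " OTU fields",
           call. = FALSE)
    if (is.na(cutoff))
      stop("line ", k, ": non-numeric cutoff label '", f[1L], "'",
           call. = FALSE)
    allIds <- unlist(otus, use.names = FALSE)
    if (anyDuplicated(allIds))
      stop("line ", k, ": id assigned to more than one OTU: ",
           paste(unique(allIds[duplicated(allIds)]), collapse = ", "),
           call. = FALSE)
    OTUAssignment(otus, cutoff = cutoff, semantics = semantics,
                  method = "imported")
  })
}
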