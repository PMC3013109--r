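# Clustering quality metrics: distance-based Calinski-Harabasz index,
# uniform-clade counts against a phylogeny, singleton statistics, and
# rank-abundance curves with area-preserving rescaling.

#' Distance-based Calinski-Harabasz index
#'
#' Variance-ratio cluster validity index generalized to pure distance data
#' (sequence space has no coordinates).  With N items in k clusters, total
#' dispersion \eqn{T = (1/N) \sum_{i<j} d^2(i,j)} over all pairs, within
#' dispersion \eqn{W = \sum_c (1/n_c) \sum_{i<j \in c} d^2(i,j)}, between
#' dispersion \eqn{B = T - W}, and
#' \deqn{CH = \frac{B / (k-1)}{W / (N-k)}.}
#' When d is Euclidean this equals the classic coordinate formula exactly
#' (the pairwise sums collapse to centroid sums of squares).  The index is
#' higher when clusters are tighter and their centers further apart, and is
#' normalized to be comparable across different k.
#'
#' @param dm A dense [DistanceMatrix-class] covering all assigned ids.
#' @param assignment An [OTUAssignment-class] with \eqn{1 < k < N}.
#' @return A single numeric; \code{Inf} when W = 0 (all clusters are sets
#'   of mutually identical sequences, common in duplicate-heavy tag data).
#' @export
chIndex <- function(dm, assignment) {
  stopifnot(is(dm, "DistanceMatrix"), is(assignment, "OTUAssignment"))
  if (isSparse(dm))
    stop("CH index needs all pairwise distances (dense matrix)",
         call. = FALSE)
  ids <- unlist(assignment@clusters, use.names = FALSE)
  missing <- setdiff(ids, dm@ids)
  if (length(missing))
    stop("assigned ids missing from the distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- length(ids)
  k <- length(assignment@clusters)
  if (k <= 1L || k >= n)
    stop("CH index is undefined for k = ", k, " clusters of n = ", n,
         " items (need 1 < k < n)", call. = FALSE)
  v2 <- dm@values[ids, ids]^2
  total <- sum(v2[upper.tri(v2)]) / n
  within <- sum(vapply(assignment@clusters, function(cl) {
    if (length(cl) < 2L) return(0)
    sub <- v2[cl, cl]
    sum(sub[upper.tri(sub)]) / length(cl)
  }, numeric(1L)))
  between <- total - within
  if (within <= 0) return(Inf)
  (between / (k - 1)) / (within / (n - k))
}

#' Count uniform clades of a phylogeny under an OTU assignment
#'
#' An internal node is \emph{uniform} iff all leaves below it carry the
#' same OTU label.  A good clustering agrees with the tree: many clades
#' are uniform.  \code{mode = "all"} counts every uniform internal node;
#' \code{mode = "maximal"} (default) counts only uniform nodes whose parent
#' is not uniform (the root counts if uniform), so a uniform clade is not
#' also credited for each of its uniform sub-clades.
#'
#' @param tree An \code{ape} \code{phylo} whose tip labels are assigned
#'   ids.
#' @param assignment An [OTUAssignment-class] covering all tip labels.
#' @param mode \code{"maximal"} or \code{"all"}.
#' @return List with \code{uniformClades} (count), \code{mode} and
#'   \code{nLeaves}.
#' @export
uniformCladeCount <- function(tree, assignment, mode = c("maximal", "all")) {
  mode <- match.arg(mode)
  if (!inherits(tree, "phylo"))
    stop("tree must be an ape 'phylo' object", call. = FALSE)
  stopifnot(is(assignment, "OTUAssignment"))
  labels <- otuLabels(assignment)
  tips <- tree$tip.label
  bad <- setdiff(tips, names(labels))
  if (length(bad))
    stop("tree leaves without an OTU label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nTip <- length(tips)
  nNode <- max(tree$edge)
  # postorder fill: nodeLabel[v] = common OTU of leaves below v, or NA
  nodeLabel <- rep(NA_integer_, nNode)
  nodeLabel[seq_len(nTip)] <- labels[tips]
  uniform <- logical(nNode)
  uniform[seq_len(nTip)] <- TRUE
  parent <- integer(nNode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # process internal nodes children-first via postorder edge traversal
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    p <- po[r, 1L]; ch <- po[r, 2L]
    if (!uniform[ch]) { uniform[p] <- FALSE; nodeLabel[p] <- NA_integer_; next }
    if (r == 1L || po[r - 1L, 1L] != p) {
      # first child seen for p: initialise
      if (is.na(nodeLabel[p])) { nodeLabel[p] <- nodeLabel[ch]; uniform[p] <- TRUE }
    }
    if (uniform[p] && !identical(nodeLabel[p], nodeLabel[ch])) {
      uniform[p] <- FALSE; nodeLabel[p] <- NA_integer_
    }
  }
  internal <- (nTip + 1L):nNode
  if (mode == "all") {
    count <- sum(uniform[internal])
  } else {
    parentUniform <- rep(FALSE, length(internal))
    hasParent <- parent[internal] != 0L
    parentUniform[hasParent] <- uniform[parent[internal][hasParent]]
    count <- sum(uniform[internal] & !parentUniform)
  }
  list(uniformClades = as.integer(count), mode = mode, nLeaves = nTip)
}

#' Singleton statistics of an assignment
#'
#' An excess of singleton OTUs (clusters of exactly one sequence) is the
#' signature of over-splitting by radius-based heuristics.
#'
#' @param assignment An [OTUAssignment-class].
#' @return Named integer vector \code{c(nOtus, nSingletons)}.
#' @export
singletonStats <- function(assignment) {
  stopifnot(is(assignment, "OTUAssignment"))
  sz <- lengths(assignment@clusters)
  c(nOtus = length(sz), nSingletons = sum(sz == 1L))
}

#' Rank abundance curve of an assignment
#'
#' Cluster sizes sorted descending; ties keep a deterministic order (by the
#' lexicographically smallest member id).
#'
#' @param assignment An [OTUAssignment-class].
#' @return A [RankAbundance-class].
#' @export
rankAbundance <- function(assignment) {
  stopifnot(is(assignment, "OTUAssignment"))
  sz <- lengths(assignment@clusters)
  mins <- vapply(assignment@clusters,
                 function(x) sort(x, method = "radix")[1L], "")
  ord <- order(-sz, mins, method = "radix")
  new("RankAbundance", abundance = as.numeric(sz[ord]), rescale = list())
}

#' Rescale a rank abundance curve to a target OTU count
#'
#' Maps ranks \eqn{x \to x K_t / K} and heights \eqn{y \to y K / K_t}, so
#' curves clustered at different distances can be compared on a common
#' axis, then resamples the scaled rank step curve at integer ranks
#' \eqn{1..K_t} by integrating it over each target rank bin.  The
#' rebinning is exactly area-preserving: the area under the step curve is
#' unchanged.
#'
#' @param curve A [RankAbundance-class].
#' @param kTarget Target number of OTUs (\eqn{\ge 1}).
#' @return A rescaled [RankAbundance-class] carrying the rescale metadata.
#' @export
rescaleRankAbundance <- function(curve, kTarget) {
  stopifnot(is(curve, "RankAbundance"))
  kTarget <- as.integer(kTarget)
  if (kTarget < 1L) stop("kTarget must be >= 1", call. = FALSE)
  a <- curve@abundance
  k <- length(a)
  yScale <- k / kTarget
  # step curve s(x) = a[ceiling(x)] on (0, k]; new bin r covers original
  # x in ((r-1) k/Kt, r k/Kt]; bar height = integral over the bin divided
  # by the original-axis bin width, then scaled by yScale * (k/Kt)/(k/Kt).
  cumA <- c(0, cumsum(a))
  stepIntegral <- function(x) {        # integral of s over (0, x]
    x <- pmin(pmax(x, 0), k)
    f <- floor(x)
    cumA[f + 1L] + (x - f) * a[pmin(f + 1L, k)]
  }
  lo <- (seq_len(kTarget) - 1L) * k / kTarget
  hi <- seq_len(kTarget) * k / kTarget
  heights <- (stepIntegral(hi) - stepIntegral(lo)) / (k / kTarget) * yScale
  heights <- pmax(heights, .Machine$double.eps)
  new("RankAbundance", abundance = heights,
      rescale = list(kOriginal = k, kTarget = kTarget,
                     xScale = kTarget / k, yScale = yScale))
}

#' Area under a rank abundance step curve
#'
#' @param curve A [RankAbundance-class].
#' @return Numeric area (each rank bar has unit width on its own axis).
#' @export
rankAbundanceArea <- function(curve) {
  stopifnot(is(curve, "RankAbundance"))
  sum(curve@abundance)
}
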