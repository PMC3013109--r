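# Synthetic fixtures with known ground truth: planted-partition gapped
# alignments, circle point sets, and random labelled trees.

#' Planted-partition gapped alignment
#'
#' Draws K center sequences at pairwise divergence close to
#' \code{deltaBetween}, then \code{nPer} members per center at divergence
#' close to \code{deltaWithin} (uniform random replacement, Jukes-Cantor
#' style, no rate heterogeneity).  A fraction \code{indelRate} of each
#' member's divergence events is realized as a gap character rather than a
#' substitution, keeping the alignment width fixed; because PSI counts a
#' gap opposite a residue as a letter, this keeps the realized pairwise
#' PSI close to the requested divergence whatever the indel share.  The
#' draw is rejected and retried (with a perturbed stream,
#' bounded retries) until the separation invariant holds under PSI
#' distance: the largest within-cluster distance is strictly below the
#' smallest between-cluster distance.  Under that invariant the planted
#' partition is exactly the complete-linkage answer for any cutoff in the
#' separation window, so parameter-recovery tests are deterministic.
#'
#' @param K Number of planted clusters.
#' @param nPer Members per cluster (default 10).
#' @param length Alignment width in columns (\eqn{\ge 50}; default 200,
#'   matching typical hypervariable-tag read lengths).
#' @param deltaWithin Within-cluster divergence (default 0.01).
#' @param deltaBetween Between-cluster divergence (default 0.20); must
#'   exceed \code{deltaWithin}.
#' @param indelRate Fraction of member divergence events realized as gaps
#'   rather than substitutions, in \[0, 1\] (default 0.2, echoing the
#'   indel-heavy error profile of pyrosequencing reads).
#' @param seed RNG seed (required for reproducibility).
#' @param maxRetries Rejection-sampling budget (default 20).
#' @return List with \code{alignment} (an [Alignment-class], ids
#'   \code{seq<cluster>_<member>}) and \code{truth} (a
#'   [SynthTruth-class]).
#' @export
plantedPartitionAlignment <- function(K, nPer = 10L, length = 200L,
                                      deltaWithin = 0.01,
                                      deltaBetween = 0.20,
                                      indelRate = 0.2, seed = 1L,
                                      maxRetries = 20L) {
  if (deltaWithin < 0 || deltaWithin >= deltaBetween || deltaBetween > 1)
    stop("need 0 <= deltaWithin < deltaBetween <= 1", call. = FALSE)
  if (indelRate < 0 || indelRate > 1)
    stop("indelRate must be a fraction in [0, 1]", call. = FALSE)
  if (length < 50L) stop("length must be >= 50", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(maxRetries)) {
    res <- .withSeed(seed + (try - 1L) * 10007L, {
      ancestor <- sample(bases, length, replace = TRUE)
      # independent changes at rate d/2 from a common source put pairs at
      # divergence ~ d (minus double-hit overlap); a gapFrac share of the
      # change events becomes a gap instead of a substitution
      mutate <- function(x, rate, gapFrac = 0) {
        hit <- which(stats::runif(length) < rate)
        if (base::length(hit)) {
          toGap <- stats::runif(base::length(hit)) < gapFrac
          x[hit[!toGap]] <- vapply(x[hit[!toGap]], function(b)
            sample(setdiff(bases, b), 1L), "")
          x[hit[toGap]] <- "-"
        }
        x
      }
      centers <- lapply(seq_len(K), function(k)
        mutate(ancestor, deltaBetween / 2))
      seqs <- character(0)
      labels <- integer(0)
      for (k in seq_len(K)) {
        for (m in seq_len(nPer)) {
          s <- mutate(centers[[k]], deltaWithin / 2, gapFrac = indelRate)
          seqs <- c(seqs, paste(s, collapse = ""))
          labels <- c(labels, k)
        }
      }
      ids <- sprintf("seq%d_%02d", labels, stats::ave(labels, labels,
                                                      FUN = seq_along))
      names(seqs) <- ids
      names(labels) <- ids
      list(aln = Alignment(seqs), labels = labels)
    })
    dm <- psiMatrix(res$aln)
    v <- as.matrix(dm)
    same <- outer(res$labels, res$labels, "==")
    diag(same) <- NA
    maxWithin <- if (nPer > 1L) max(v[which(same)], na.rm = TRUE) else 0
    minBetween <- if (K > 1L) min(v[which(!same)]) else Inf
    if (maxWithin < minBetween) {
      truth <- new("SynthTruth", labels = res$labels,
                   params = list(K = K, nPer = nPer, length = length,
                                 deltaWithin = deltaWithin,
                                 deltaBetween = deltaBetween,
                                 indelRate = indelRate, seed = seed,
                                 retries = try - 1L,
                                 maxWithin = maxWithin,
                                 minBetween = minBetween,
                                 meanWithin = if (nPer > 1L)
                                   mean(v[which(same)]) else NA_real_,
                                 meanBetween = if (K > 1L)
                                   mean(v[which(!same)]) else NA_real_))
      return(list(alignment = res$aln, truth = truth))
    }
  }
  stop("could not achieve cluster separation after ", maxRetries,
       " retries; widen the gap between deltaWithin and deltaBetween",
       call. = FALSE)
}

#' Circle point-set distance matrix
#'
#' n points on a circle of radius 1 (evenly spaced plus a small seeded
#' angular jitter), returned as their Euclidean distance matrix.  This is
#' the classic plane fixture on which greedy radius clustering at radius 1
#' splits the set while complete linkage at the observed diameter finds a
#' single cluster.
#'
#' @param n Number of points (\eqn{\ge 3}).
#' @param seed RNG seed for the jitter.
#' @return A dense [DistanceMatrix-class] with ids \code{P01..Pn}; the
#'   point coordinates are attached as attribute \code{"coords"}.
#' @export
circlePointsMatrix <- function(n, seed = 1L) {
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  theta <- .withSeed(seed, {
    2 * pi * (seq_len(n) - 1L) / n + stats::rnorm(n, sd = 0.2 * pi / n)
  })
  xy <- cbind(cos(theta), sin(theta))
  ids <- sprintf("P%02d", seq_len(n))
  rownames(xy) <- ids
  dm <- DistanceMatrix(as.matrix(stats::dist(xy)), ids)
  attr(dm, "coords") <- xy
  dm
}

#' Random labelled tree
#'
#' Random rooted topology (via \code{ape::rtree}) with exponential branch
#' lengths and unique leaf labels, deterministic per seed.
#'
#' @param nLeaves Number of leaves (\eqn{\ge 2}).
#' @param seed RNG seed.
#' @param meanBranch Mean of the exponential branch length distribution.
#' @return An \code{ape} \code{phylo} with tip labels \code{t1..tn}.
#' @export
randomLabeledTree <- function(nLeaves, seed = 1L, meanBranch = 0.1) {
  if (nLeaves < 2L) stop("need at least 2 leaves", call. = FALSE)
  .withSeed(seed, {
    ape::rtree(nLeaves, rooted = TRUE,
               br = function(k) stats::rexp(k, rate = 1 / meanBranch))
  })
}
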