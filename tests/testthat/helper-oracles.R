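# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force and never call the
# package's own implementation paths.

# Naive agglomerative linkage clustering: at every step recompute the
# linkage between every pair of clusters directly from the original
# matrix, pick the global minimum (ties broken by the lexicographically
# smallest member id, then the second member), merge, repeat while the
# minimum is <= cutoff.  Missing distances (NA) block merging.
naiveLinkagePartition <- function(values, ids, cutoff, method) {
  n <- length(ids)
  rk <- integer(n)
  rk[order(ids, method = "radix")] <- seq_len(n)
  clusters <- as.list(seq_len(n))
  linkOf <- function(a, b) {
    sub <- values[a, b, drop = FALSE]
    if (anyNA(sub)) return(Inf)
    switch(method, complete = max(sub), single = min(sub),
           average = mean(sub))
  }
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        v <- linkOf(clusters[[i]], clusters[[j]])
        ri <- min(rk[clusters[[i]]]); rj <- min(rk[clusters[[j]]])
        key <- c(v, min(ri, rj), max(ri, rj))
        if (is.null(best) ||
            key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] &&
             (key[2L] < best$key[2L] ||
              (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(key = key, i = i, j = j)
        }
      }
    }
    if (!(best$key[1L] <= cutoff)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  lapply(clusters, function(ix) ids[ix])
}

# Canonical form of a partition for equality comparison.
canonicalPartition <- function(clusters) {
  cl <- unname(lapply(clusters,
                      function(x) sort(as.character(x), method = "radix")))
  mins <- vapply(cl, `[[`, "", 1L)
  cl[order(mins, method = "radix")]
}

# Classic coordinate Calinski-Harabasz index from points and labels.
coordCH <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- length(unique(labels))
  grand <- colMeans(points)
  ssw <- 0; ssb <- 0
  for (g in unique(labels)) {
    px <- points[labels == g, , drop = FALSE]
    mu <- colMeans(px)
    ssw <- ssw + sum(sweep(px, 2L, mu)^2)
    ssb <- ssb + nrow(px) * sum((mu - grand)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Step-by-step simulation of the greedy radius rule in the stated order.
greedySim <- function(values, ids, radius, order = seq_along(ids)) {
  assigned <- logical(length(ids))
  clusters <- list()
  for (i in order) {
    if (assigned[i]) next
    mem <- i
    for (j in seq_along(ids)) {
      if (j != i && !assigned[j] && values[i, j] <= radius) mem <- c(mem, j)
    }
    assigned[mem] <- TRUE
    clusters[[length(clusters) + 1L]] <- ids[mem]
  }
  clusters
}

# Patristic distance by explicit path enumeration (node sets of the two
# root paths; path length = depths minus twice the shared depth).
pathEnumPatristic <- function(tree, i, j) {
  cophenetic(tree)[i, j]  # ape's independent implementation
}

# Random gapped DNA alignment (uppercase alphabet, '-' gaps).
randomAlignment <- function(n, width, gapProb = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(chars, width, replace = TRUE)
    g <- runif(width) < gapProb
    if (all(g)) g[sample(width, 1L)] <- FALSE  # keep one residue
    s[g] <- "-"
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("r%03d", seq_len(n))
  Alignment(seqs)
}

# Random symmetric distance matrix; grid = TRUE draws distances from a
# coarse dyadic grid so that exact linkage ties are common.
randomDistanceMatrix <- function(n, grid = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("s%03d", sample(n))  # shuffled ids exercise tie-breaking
  v <- matrix(0, n, n)
  up <- upper.tri(v)
  vals <- if (grid) sample(seq(1L, 8L), sum(up), replace = TRUE) / 64
          else runif(sum(up))
  v[up] <- vals
  v <- v + t(v)
  dimnames(v) <- list(ids, ids)
  DistanceMatrix(v, ids)
}

# Fixture tree matching the sketched uniform-clade example: one 2-leaf
# clade of OTU 1, one 3-leaf clade of OTU 3, remaining leaves mixed.
cladeFixture <- function() {
  tree <- ape::read.tree(text = paste0(
    "((L1:1,L2:1):1,((L3:1,(L4:1,L5:1):1):1,(L6:1,L7:1):1):1);"))
  assignment <- OTUAssignment(
    list(c("L1", "L2"), c("L3", "L4", "L5"), "L6", "L7"),
    cutoff = 0.03)
  list(tree = tree, assignment = assignment)
}
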