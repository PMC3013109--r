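# Calinski-Harabasz index, uniform clades, singletons, rank abundance.

euclideanDM <- function(points, ids = rownames(points)) {
  DistanceMatrix(as.matrix(stats::dist(points)), ids)
}

test_that("distance-based CH equals the coordinate formula on Euclidean data", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  labels <- c(1, 1, 2, 2)
  dm <- euclideanDM(x)
  a <- OTUAssignment(list(c("p1", "p2"), c("p3", "p4")), cutoff = 0.2)
  expect_equal(chIndex(dm, a), coordCH(x, labels), tolerance = 1e-12)

  set.seed(53)
  for (k in 2:5) {
    pts <- matrix(rnorm(40 * 3), ncol = 3)
    rownames(pts) <- sprintf("x%02d", 1:40)
    labels <- sample(k, 40, replace = TRUE)
    while (length(unique(labels)) < k) labels <- sample(k, 40, replace = TRUE)
    asg <- OTUAssignment(split(rownames(pts), labels), cutoff = 0.1)
    expect_equal(chIndex(euclideanDM(pts), asg), coordCH(pts, labels),
                 tolerance = 1e-9)
  }
})

test_that("CH diverges for perfect clusters and rejects degenerate k", {
  x <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(c("d1", "d2", "d3", "d4"), NULL))
  dm <- euclideanDM(x)
  a <- OTUAssignment(list(c("d1", "d2"), c("d3", "d4")), cutoff = 0.1)
  expect_identical(chIndex(dm, a), Inf)
  one <- OTUAssignment(list(c("d1", "d2", "d3", "d4")), cutoff = 1)
  expect_error(chIndex(dm, one), "1 < k < n")
  allS <- OTUAssignment(as.list(rownames(x)), cutoff = 0)
  expect_error(chIndex(dm, allS), "1 < k < n")
  sp <- DistanceMatrix(matrix(c(0, NA, NA, 0), 2,
                              dimnames = list(c("d1", "d2"),
                                              c("d1", "d2"))),
                       c("d1", "d2"), sparseCutoff = 0.1)
  expect_error(chIndex(sp, a), "dense")
})

test_that("random relabeling lowers CH on a well-separated planted partition", {
  set.seed(59)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  pts <- centers[rep(1:3, each = 8), ] + matrix(rnorm(48, sd = 0.3), ncol = 2)
  rownames(pts) <- sprintf("y%02d", 1:24)
  truth <- rep(1:3, each = 8)
  dm <- euclideanDM(pts)
  aTrue <- OTUAssignment(split(rownames(pts), truth), cutoff = 1)
  chTrue <- chIndex(dm, aTrue)
  for (rep in 1:5) {
    shuffled <- sample(truth)
    while (length(unique(shuffled)) < 3) shuffled <- sample(truth)
    aShuf <- OTUAssignment(split(rownames(pts), shuffled), cutoff = 1)
    expect_lt(chIndex(dm, aShuf), chTrue)
  }
})

test_that("CH over the dendrogram cut peaks at the planted K", {
  # within-cluster spread must be resolvable at the read length, otherwise
  # sub-splitting near-duplicate reads drives W toward 0 and CH explodes
  pp <- plantedPartitionAlignment(K = 4, nPer = 10, length = 300,
                                  deltaWithin = 0.04, deltaBetween = 0.30,
                                  seed = 61)
  dm <- psiMatrix(pp$alignment)
  res <- linkageCluster(dm, cutoffs = seq(0.02, 0.40, by = 0.02))
  ch <- vapply(res$assignments, function(a) {
    k <- nOtus(a)
    if (k <= 1L || k >= length(seqIds(dm))) return(NA_real_)
    chIndex(dm, a)
  }, numeric(1))
  ks <- vapply(res$assignments, nOtus, 0L)
  best <- ks[which.max(ch)]
  expect_equal(unname(best), 4L)
})

test_that("uniform clade counting matches the sketched fixture", {
  fx <- cladeFixture()
  r <- uniformCladeCount(fx$tree, fx$assignment)
  expect_equal(r$uniformClades, 2L)
  expect_equal(r$mode, "maximal")
  # counting nested uniform clades too adds the (L4,L5) cherry
  rAll <- uniformCladeCount(fx$tree, fx$assignment, mode = "all")
  expect_equal(rAll$uniformClades, 3L)
})

test_that("uniform clade edge cases: single OTU, all singletons", {
  tr <- randomLabeledTree(8, seed = 3)
  one <- OTUAssignment(list(tr$tip.label), cutoff = 0.1)
  expect_equal(uniformCladeCount(tr, one)$uniformClades, 1L)  # the root
  expect_gt(uniformCladeCount(tr, one, mode = "all")$uniformClades, 1L)
  sing <- OTUAssignment(as.list(tr$tip.label), cutoff = 0)
  expect_equal(uniformCladeCount(tr, sing)$uniformClades, 0L)
  expect_equal(uniformCladeCount(tr, sing, mode = "all")$uniformClades, 0L)
  bad <- OTUAssignment(as.list(tr$tip.label[-1]), cutoff = 0)
  expect_error(uniformCladeCount(tr, bad), "without an OTU label")
})

test_that("mode=all counts at least as many clades as mode=maximal", {
  for (s in 1:25) {
    tr <- randomLabeledTree(sample(4:16, 1L), seed = 200 + s)
    k <- sample(seq_len(length(tr$tip.label)), 1L)
    labels <- sample(k, length(tr$tip.label), replace = TRUE)
    asg <- OTUAssignment(split(tr$tip.label, labels), cutoff = 0.05)
    nAll <- uniformCladeCount(tr, asg, mode = "all")$uniformClades
    nMax <- uniformCladeCount(tr, asg, mode = "maximal")$uniformClades
    expect_gte(nAll, nMax)
    expect_lte(nAll, tr$Nnode)
  }
})

test_that("singleton statistics count size-1 OTUs", {
  a <- OTUAssignment(list(c("a", "b", "c"), "d", "e"), cutoff = 0.03)
  expect_equal(singletonStats(a), c(nOtus = 3L, nSingletons = 2L))
  none <- OTUAssignment(list(c("a", "b"), c("c", "d")), cutoff = 0.03)
  expect_equal(singletonStats(none)[["nSingletons"]], 0L)
  all <- OTUAssignment(as.list(letters[1:5]), cutoff = 0.03)
  expect_equal(singletonStats(all), c(nOtus = 5L, nSingletons = 5L))
})

test_that("rank abundance sorts sizes descending and preserves the total", {
  a <- OTUAssignment(list(c("a", "b"), c("c", "d", "e", "f", "g"), "h"),
                     cutoff = 0.03)
  ra <- rankAbundance(a)
  expect_equal(abundances(ra), c(5, 2, 1))
  expect_equal(sum(abundances(ra)), 8)
  sing <- OTUAssignment(as.list(letters[1:6]), cutoff = 0)
  expect_equal(abundances(rankAbundance(sing)), rep(1, 6))
})

test_that("rescaling is the identity at K and matches the worked example", {
  ra <- rankAbundance(OTUAssignment(
    list(c("a", "b", "c", "d"), c("e", "f")), cutoff = 0.03))
  expect_equal(abundances(ra), c(4, 2))
  same <- rescaleRankAbundance(ra, 2L)
  expect_equal(abundances(same), c(4, 2), tolerance = 1e-12)
  up <- rescaleRankAbundance(ra, 4L)
  expect_equal(abundances(up), c(2, 2, 1, 1))
  expect_equal(rankAbundanceArea(up), rankAbundanceArea(ra))
})

test_that("rescaling conserves step-curve area on random curves", {
  set.seed(67)
  for (rep in 1:30) {
    sizes <- sort(sample(1:50, sample(3:20, 1L), replace = TRUE),
                  decreasing = TRUE)
    ra <- new("RankAbundance", abundance = as.numeric(sizes),
              rescale = list())
    kt <- sample(2:40, 1L)
    rs <- rescaleRankAbundance(ra, kt)
    expect_equal(rankAbundanceArea(rs), rankAbundanceArea(ra),
                 tolerance = 0.01 * rankAbundanceArea(ra))
    expect_true(all(diff(abundances(rs)) <= 1e-9))
  }
})
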