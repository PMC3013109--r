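# Linkage and greedy clustering, list-file IO, determinism guarantees.

test_that("cutoff extremes give one cluster / all singletons", {
  set.seed(2)
  dm <- randomDistanceMatrix(12)
  v <- as.matrix(dm)
  one <- linkageCluster(dm, cutoffs = max(v))$assignments[[1]]
  expect_equal(nOtus(one), 1L)
  offDiag <- v[upper.tri(v)]
  sing <- linkageCluster(dm, cutoffs = min(offDiag) * 0.99)$assignments[[1]]
  expect_equal(nOtus(sing), 12L)
})

test_that("two tight pairs at cutoff 0.03 stay separate", {
  ids <- c("A", "B", "C", "D")
  v <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  v["A", "B"] <- v["B", "A"] <- 0.01
  v["C", "D"] <- v["D", "C"] <- 0.01
  diag(v) <- 0
  dm <- DistanceMatrix(v, ids)
  a <- linkageCluster(dm, 0.03)$assignments[[1]]
  expect_equal(canonicalPartition(otuClusters(a)),
               list(c("A", "B"), c("C", "D")))
})

test_that("linkage matches the naive oracle on random and tie-heavy matrices", {
  # the full sweep lives in the acceptance suite; spot-check here
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(5:25, 1L)
    dm <- randomDistanceMatrix(n, grid = rep %% 2 == 0)
    method <- c("complete", "single", "average")[1L + rep %% 3]
    cutoff <- stats::quantile(as.matrix(dm)[upper.tri(as.matrix(dm))], 0.5)
    mine <- linkageCluster(dm, cutoff, method = method)$assignments[[1]]
    oracle <- naiveLinkagePartition(as.matrix(dm), seqIds(dm), cutoff, method)
    expect_identical(canonicalPartition(otuClusters(mine)),
                     canonicalPartition(oracle))
  }
})

test_that("a run yields the whole cutoff series with non-increasing OTU counts", {
  set.seed(23)
  dm <- randomDistanceMatrix(30)
  cutoffs <- c(0.03, 0.05, 0.07, 0.2, 0.5, 0.9)
  res <- linkageCluster(dm, cutoffs)
  counts <- vapply(res$assignments, nOtus, 0L)
  expect_true(all(diff(counts) <= 0))
  h <- mergeTable(res$dendrogram)$height
  expect_true(all(diff(h) >= -1e-12))
  # each cut equals a fresh single-cutoff run
  alone <- linkageCluster(dm, 0.07)$assignments[[1]]
  expect_identical(canonicalPartition(otuClusters(res$assignments[["0.07"]])),
                   canonicalPartition(otuClusters(alone)))
})

test_that("complete linkage bounds every intra-cluster pair by the cutoff", {
  set.seed(29)
  for (rep in 1:10) {
    dm <- randomDistanceMatrix(sample(8:30, 1L))
    cutoff <- stats::runif(1, 0.2, 0.8)
    a <- linkageCluster(dm, cutoff)$assignments[[1]]
    v <- as.matrix(dm)
    for (cl in otuClusters(a)) {
      if (length(cl) > 1L)
        expect_lte(max(v[cl, cl]), cutoff)
    }
  }
})

test_that("sparse matrices block merges across omitted pairs", {
  ids <- c("A", "B", "C")
  v <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  diag(v) <- 0
  v["A", "B"] <- v["B", "A"] <- 0.01
  v["B", "C"] <- v["C", "B"] <- 0.02
  dm <- DistanceMatrix(v, ids, sparseCutoff = 0.03)
  a <- linkageCluster(dm, 0.5)$assignments[[1]]
  # d(A,C) unknown -> treated as beyond any cutoff -> C cannot join {A,B}
  expect_equal(canonicalPartition(otuClusters(a)),
               list(c("A", "B"), "C"))
  # single linkage would chain through the known pair
  s <- linkageCluster(dm, 0.5, method = "single")$assignments[[1]]
  expect_equal(nOtus(s), 1L)
})

test_that("greedy clustering follows the seed rule", {
  set.seed(37)
  dm <- randomDistanceMatrix(10)
  v <- as.matrix(dm)
  one <- greedyCluster(dm, radius = max(v))
  expect_equal(nOtus(one), 1L)
  expect_equal(cutoffSemantics(one), "radius")
  allSing <- greedyCluster(dm, radius = 0)
  expect_equal(nOtus(allSing), 10L)
  # input order equals the step-by-step simulation
  r <- 0.4
  mine <- greedyCluster(dm, radius = r)
  oracle <- greedySim(v, seqIds(dm), r)
  expect_identical(canonicalPartition(otuClusters(mine)),
                   canonicalPartition(oracle))
  # member-to-seed distance is within the radius
  for (cl in otuClusters(mine)) {
    seed <- cl[1L]
    expect_true(all(v[seed, cl] <= r))
  }
  expect_error(greedyCluster(dm, radius = -1), "non-negative")
})

test_that("greedy clusters can span twice the radius", {
  ids <- c("L", "M", "R")       # M in the middle of a 2r-long segment
  v <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, dimnames = list(ids, ids))
  dm <- DistanceMatrix(v, ids)
  # seed order starting at M absorbs both ends at radius 1
  a <- greedyCluster(dm, radius = 1)
  lab <- otuLabels(a)
  expect_equal(nOtus(a), 2L)  # input order: L first -> {L,M}, {R}
  vRand <- greedyCluster(DistanceMatrix(v[c(2, 1, 3), c(2, 1, 3)],
                                        ids[c(2, 1, 3)]), radius = 1)
  expect_equal(nOtus(vRand), 1L)
  witness <- otuClusters(vRand)[[1L]]
  expect_equal(max(v[witness, witness]), 2)   # intra pair at 2 * radius
})

test_that("random seed order is reproducible", {
  set.seed(41)
  dm <- randomDistanceMatrix(15)
  a1 <- greedyCluster(dm, radius = 0.3, order = "random", seed = 5L)
  a2 <- greedyCluster(dm, radius = 0.3, order = "random", seed = 5L)
  expect_identical(otuClusters(a1), otuClusters(a2))
})

test_that("mothur-style list files round-trip", {
  a1 <- OTUAssignment(list(c("s1", "s2"), "s3"), cutoff = 0.03,
                      method = "complete")
  a2 <- OTUAssignment(list(c("s1", "s2", "s3")), cutoff = 0.05,
                      method = "complete")
  f <- withr::local_tempfile(fileext = ".list")
  writeOtus(list(a1, a2), f)
  lines <- readLines(f)
  expect_equal(length(lines), 2L)
  expect_equal(strsplit(lines[1L], "\t")[[1L]][2L], "2")
  back <- readOtus(f)
  expect_equal(otuCutoff(back[[1L]]), 0.03)
  expect_identical(canonicalPartition(otuClusters(back[[1L]])),
                   canonicalPartition(otuClusters(a1)))
  expect_identical(canonicalPartition(otuClusters(back[[2L]])),
                   canonicalPartition(otuClusters(a2)))

  dup <- withr::local_tempfile(fileext = ".list")
  writeLines("0.03\t2\ts1,s2\ts2", dup)
  expect_error(readOtus(dup), "line 1.*more than one OTU")
  malformed <- withr::local_tempfile(fileext = ".list")
  writeLines("0.03\t3\ts1,s2\ts3", malformed)
  expect_error(readOtus(malformed), "line 1")
})

test_that("clustering rejects degenerate inputs", {
  dm <- randomDistanceMatrix(5, seed = 1)
  expect_error(linkageCluster(dm, numeric(0)), "cutoff")
  expect_error(linkageCluster(dm, -0.1), "non-negative")
  expect_error(linkageCluster(dm, c(0.5, 0.3)), "ascending")
})
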