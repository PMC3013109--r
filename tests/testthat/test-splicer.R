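# Cut / dereplicate / splice round trips for hand curation.

# curated alignment built from the original in-span columns: one gapped
# row per snippet class, taken from its first member
curatedFromOriginal <- function(aln, span, snippets) {
  s <- IRanges::start(span); e <- IRanges::end(span)
  mem <- snippetMembership(snippets)
  rows <- vapply(seq_along(uniqueSnippets(snippets)), function(k) {
    id <- names(mem)[mem == k][1L]
    substr(as.character(aln)[[id]], s, e)
  }, "")
  Alignment(stats::setNames(rows, sprintf("snippet_%d", seq_along(rows))))
}

test_that("cut dereplicates in-span snippets (6 members, 4 distinct)", {
  aln <- Alignment(c(
    r1 = "AAACGTTT", r2 = "AAACGTTT", r3 = "AAAC-TTT",
    r4 = "AAAG-TTT", r5 = "AAA--TTT", r6 = "AAACGTTT"))
  res <- spliceCut(aln, IRanges::IRanges(4L, 5L))
  snip <- res$snippets
  expect_equal(length(uniqueSnippets(snip)), 4L)
  # decreasing membership count, ties by string: CG x3, then "", C, G x1
  expect_equal(uniqueSnippets(snip), c("CG", "", "C", "G"))
  expect_equal(unname(snippetMembership(snip)[c("r1", "r3", "r4", "r5")]),
               c(1L, 3L, 4L, 2L))
  # fully gapped in-span -> empty-string snippet class
  expect_equal(uniqueSnippets(snip)[snippetMembership(snip)[["r5"]]], "")
})

test_that("all-identical snippets collapse to one", {
  aln <- Alignment(c(a = "GGAAGG", b = "GGAAGG", c = "GGAAGG"))
  res <- spliceCut(aln, IRanges::IRanges(3L, 4L))
  expect_equal(uniqueSnippets(res$snippets), "AA")
})

test_that("cut rejects empty or out-of-range spans", {
  aln <- Alignment(c(a = "ACGT"))
  expect_error(spliceCut(aln, IRanges::IRanges(3L, 9L)), "span")
  expect_error(spliceCut(aln, c(4, 2)), "span")
})

test_that("cut then splice with unedited columnization is the identity", {
  set.seed(3)
  for (rep in 1:40) {
    aln <- randomAlignment(sample(3:8, 1L), sample(8:20, 1L))
    w <- alignmentWidth(aln)
    a <- sample(seq_len(w), 1L); b <- min(w, a + sample(0:6, 1L))
    span <- IRanges::IRanges(a, b)
    pieces <- spliceCut(aln, span)
    curated <- curatedFromOriginal(aln, span, pieces$snippets)
    back <- spliceMerge(pieces$leftFlank, curated, pieces$snippets,
                        pieces$rightFlank)
    # flanks and degapped content are always restored exactly
    expect_identical(gsub("-", "", as.character(back), fixed = TRUE),
                     gsub("-", "", as.character(aln), fixed = TRUE))
    expect_identical(substr(as.character(back), 1L, a - 1L),
                     substr(as.character(aln), 1L, a - 1L))
    # dereplication canonicalizes the in-span columnization to the class
    # representative; when every class is column-consistent the round
    # trip is the exact identity
    mem <- snippetMembership(pieces$snippets)
    inSpan <- substr(as.character(aln), a, b)
    consistent <- all(vapply(split(inSpan[names(mem)], mem),
                             function(x) length(unique(x)) == 1L,
                             logical(1)))
    if (consistent)
      expect_identical(as.character(back), as.character(aln))
  }
  # gap-free spans are always column-consistent: exact round trip
  set.seed(4)
  for (rep in 1:10) {
    aln <- randomAlignment(5, 15, gapProb = 0)
    pieces <- spliceCut(aln, IRanges::IRanges(6L, 10L))
    curated <- curatedFromOriginal(aln, IRanges::IRanges(6L, 10L),
                                   pieces$snippets)
    back <- spliceMerge(pieces$leftFlank, curated, pieces$snippets,
                        pieces$rightFlank)
    expect_identical(as.character(back), as.character(aln))
  }
})

test_that("curated rows may widen the span; content is preserved", {
  aln <- Alignment(c(q1 = "TTACGTT", q2 = "TTAC-TT",
                     q3 = "TT--GTT", q4 = "TTACGTT"))
  span <- IRanges::IRanges(3L, 5L)           # 3-column span
  pieces <- spliceCut(aln, span)
  widen <- function(x) paste0("-", x, "-")   # recolumnize over 5 columns
  curated <- Alignment(stats::setNames(
    vapply(seq_along(uniqueSnippets(pieces$snippets)), function(k) {
      id <- names(snippetMembership(pieces$snippets))[
        snippetMembership(pieces$snippets) == k][1L]
      widen(substr(as.character(aln)[[id]], 3L, 5L))
    }, ""), paste0("c", 1:3)))
  out <- spliceMerge(pieces$leftFlank, curated, pieces$snippets,
                     pieces$rightFlank)
  expect_equal(alignmentWidth(out), 7L + 2L)
  expect_identical(gsub("-", "", as.character(out), fixed = TRUE),
                   gsub("-", "", as.character(aln), fixed = TRUE))
})

test_that("splice rejects mismatched curated rows", {
  aln <- Alignment(c(a = "AACGAA", b = "AAGGAA"))
  pieces <- spliceCut(aln, IRanges::IRanges(3L, 4L))
  tooFew <- Alignment(c(x = "CG"))
  expect_error(spliceMerge(pieces$leftFlank, tooFew, pieces$snippets,
                           pieces$rightFlank), "unique snippets")
  wrong <- Alignment(c(x = "C-G", y = "T-T"))
  expect_error(spliceMerge(pieces$leftFlank, wrong, pieces$snippets,
                           pieces$rightFlank), "row 2")
})

test_that("dereplication is bounded by the sequence count", {
  set.seed(21)
  for (rep in 1:20) {
    aln <- randomAlignment(sample(2:10, 1L), 12)
    pieces <- spliceCut(aln, IRanges::IRanges(4L, 9L))
    nu <- length(uniqueSnippets(pieces$snippets))
    expect_lte(nu, length(aln))
    snips <- vapply(seq_len(length(aln)), function(i)
      gsub("-", "", substr(as.character(aln)[[i]], 4L, 9L), fixed = TRUE),
      "")
    expect_equal(nu, length(unique(snips)))
  }
})

test_that("snippet exchange files are written with count-bearing names", {
  aln <- Alignment(c(a = "AAACGTTT", b = "AAACGTTT", c = "AAAG-TTT"))
  pieces <- spliceCut(aln, IRanges::IRanges(4L, 5L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSnippets(pieces$snippets, fa, tsv)
  back <- Biostrings::readBStringSet(fa)   # snippets are ragged, not an Alignment
  expect_equal(names(back), c("snippet_1_n2", "snippet_2_n1"))
  expect_equal(as.character(back[["snippet_1_n2"]]), "CG")
  mem <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(mem$snippet, c(1L, 1L, 2L))
})
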