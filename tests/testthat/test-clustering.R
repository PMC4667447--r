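# cd-hit-style identity, greedy clustering, longest-ORF representatives.

test_that("pairwise identity follows the shorter-sequence / best-orientation convention", {
  set.seed(12)
  a <- randSeq(100)
  expect_equal(pairwiseIdentity(a, a), 1.0)
  # two substitutions in 100 -> 0.98
  b <- a
  substr(b, 10L, 10L) <- if (substr(a, 10, 10) == "A") "C" else "A"
  substr(b, 60L, 60L) <- if (substr(a, 60, 60) == "G") "T" else "G"
  expect_equal(pairwiseIdentity(a, b), 0.98)
  # containment scores 1.0 on the shorter denominator
  long <- randSeq(200)
  expect_equal(pairwiseIdentity(substr(long, 50L, 99L), long), 1.0)
  # reverse-complement orientation is taken at nucleotide level
  expect_equal(pairwiseIdentity(rcOracle(a), a), 1.0)
  # protein level is forward-only
  expect_equal(pairwiseIdentity("MKLVV", "MKLVV", level = "aa"), 1.0)
})

test_that("greedy clustering recovers planted families exactly and matches the all-pairs oracle", {
  fix <- plantFamiliesFixture(nFamilies = 10L, familySize = 5L,
                              len = 500L, identity = 0.99, seed = 42L)
  cl <- greedyCluster(fix$seqs, threshold = 0.98, level = "nt")
  expect_equal(length(cl), 10L)
  got <- lapply(clusterMembers(cl), sort)
  expect_setequal(unname(got), fix$families)
  # identical membership to the oracle clustering
  oracle <- oracleGreedyCluster(fix$seqs, 0.98)
  expect_equal(got[order(names(got))], oracle[order(names(oracle))])
})

test_that("clustering partitions the input and is monotone in the threshold", {
  fix <- plantFamiliesFixture(nFamilies = 4L, familySize = 3L, len = 300L,
                              identity = 0.99, seed = 9L)
  sizes <- vapply(c(0.90, 0.95, 0.98, 1.00), function(th) {
    cl <- greedyCluster(fix$seqs, th, level = "nt")
    ids <- unlist(clusterMembers(cl), use.names = FALSE)
    expect_setequal(ids, names(fix$seqs))   # partition: every id exactly once
    expect_equal(length(ids), length(fix$seqs))
    length(cl)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("threshold 1.0 groups exactly the duplicate sequences", {
  set.seed(33)
  uniq <- setNames(vapply(1:6, function(i) randSeq(150), character(1)),
                   sprintf("u%d", 1:6))
  seqs <- c(uniq, setNames(uniq[c(2L, 5L)], c("copy2", "copy5")))
  cl <- greedyCluster(seqs, 1.0, level = "nt")
  # hash-based dedup oracle
  expect_equal(length(cl), length(unique(unname(seqs))))
  got <- lapply(clusterMembers(cl), sort)
  oracle <- lapply(split(names(seqs), unname(seqs)), sort)
  expect_setequal(unname(got), unname(oracle))
})

test_that("longest-ORF representative selection applies ORF length then contig length", {
  cl <- methods::new("ContigClusters",
                     representatives = c("a", "s"),
                     members = list(c("a", "b"), "s"),
                     level = "aa", threshold = 0.9)
  orf <- c(a = 300, b = 450, s = 90)
  len <- c(a = 2000, b = 900, s = 400)
  expect_equal(selectByLongestOrf(cl, orf, len), c("b", "s"))
  # ORF tie -> longer contig
  orf2 <- c(a = 300, b = 300, s = 90)
  len2 <- c(a = 900, b = 1200, s = 400)
  expect_equal(selectByLongestOrf(cl, orf2, len2)[1L], "b")

  # randomized clusters vs a brute-force argmax oracle
  set.seed(55)
  for (rep in 1:200) {
    n <- sample(2:6, 1L)
    ids <- sprintf("m%d", 1:n)
    orfL <- setNames(sample(0:500, n, TRUE) %/% 3 * 3, ids)
    ctgL <- setNames(orfL + sample(0:800, n, TRUE), ids)
    cl1 <- methods::new("ContigClusters", representatives = ids[1L],
                        members = list(ids), level = "aa", threshold = 0.9)
    pick <- selectByLongestOrf(cl1, orfL, ctgL)
    ord <- order(-orfL, -ctgL, ids)
    expect_equal(unname(pick), ids[ord[1L]])
  }
})
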