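# Per-locus representative selection, antisense chimera handling, length
# filter, sample merging.

test_that("locus representative maximizes (length, depth) with documented tie-breaks", {
  m <- data.frame(id = c("a", "b"), length = c(500L, 400L),
                  depth = c(10, 90), transcriptIndex = c(1L, 2L))
  expect_equal(selectLocusRepresentative(m), "a")          # length first
  expect_equal(selectLocusRepresentative(m, key = "depth,len"), "b")
  m2 <- data.frame(id = c("x", "y"), length = c(400L, 400L),
                   depth = c(5, 5), transcriptIndex = c(2L, 1L))
  expect_equal(selectLocusRepresentative(m2), "y")         # transcript index
  expect_equal(selectLocusRepresentative(m2[1L, ]), "x")   # singleton

  # randomized groups against an exhaustive pairwise-comparison oracle
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(2:6, 1L)
    g <- data.frame(id = sprintf("m%d", 1:n),
                    length = sample(200:1000, n, TRUE),
                    depth = sample(1:50, n, TRUE),
                    transcriptIndex = sample.int(n))
    pick <- selectLocusRepresentative(g)
    # oracle: a member beaten by no other under (length, depth, index, id)
    beats <- function(i, j)
      g$length[i] > g$length[j] ||
      (g$length[i] == g$length[j] && g$depth[i] > g$depth[j]) ||
      (g$length[i] == g$length[j] && g$depth[i] == g$depth[j] &&
       g$transcriptIndex[i] < g$transcriptIndex[j])
    unbeaten <- which(vapply(seq_len(n), function(i)
      !any(vapply(seq_len(n)[-i], function(j) beats(j, i), logical(1))),
      logical(1)))
    expect_true(pick %in% g$id[unbeaten])
  }
})

test_that("locus grouping keeps one representative per locus and passes unparsed ids through", {
  set.seed(2)
  seqs <- c(L1a = randSeq(300), L1b = randSeq(500), L2a = randSeq(400),
            plain = randSeq(250))
  meta <- data.frame(id = names(seqs),
                     locus = c("1", "1", "2", NA),
                     transcriptIndex = c(1L, 2L, 1L, NA),
                     stringsAsFactors = FALSE)
  kept <- locusRepresentatives(seqs, meta)
  expect_setequal(names(kept), c("L1b", "L2a", "plain"))
})

test_that("a planted antisense chimera is split near the true junction", {
  set.seed(31)
  S <- randSeq(300)
  chim <- paste0(S, rcOracle(S))
  call <- detectAntisenseChimera(chim, seedLen = 12L, minMatch = 60L)
  expect_equal(call$action, "split")
  expect_lte(abs(call$junction - 300L), 12L)  # within seed resolution
  # fragments too short to split -> removed
  S2 <- randSeq(150)
  call2 <- detectAntisenseChimera(paste0(S2, rcOracle(S2)),
                                  minFragmentLen = 200L)
  expect_equal(call2$action, "removed")
  # short palindrome-free contig cannot reach minMatch
  expect_equal(detectAntisenseChimera(randSeq(100), minMatch = 60L)$action,
               "intact")
})

test_that("chimera detection has a low false-positive rate and split outputs re-test intact", {
  set.seed(77)
  calls <- vapply(1:200, function(i)
    detectAntisenseChimera(randSeq(600))$action, character(1))
  expect_lt(mean(calls != "intact"), 0.01)

  S <- randSeq(400)
  res <- processChimeras(c(chimera = paste0(S, rcOracle(S)),
                           ok = randSeq(500)))
  expect_setequal(res$report$action, c("split", "intact"))
  again <- processChimeras(res$contigs)
  expect_true(all(again$report$action == "intact"))
})

test_that("length filter is inclusive at the threshold and idempotent", {
  set.seed(4)
  ctg <- setNames(vapply(c(199L, 200L, 201L), randSeq, character(1)),
                  c("a", "b", "c"))
  kept <- lengthFilter(ctg, 200L)
  expect_setequal(names(kept), c("b", "c"))
  expect_equal(unname(attr(kept, "report")["dropped"]), 1L)
  kept2 <- lengthFilter(kept, 200L)
  expect_equal(names(kept2), names(kept))
  expect_equal(names(lengthFilter(ctg, 1L)), names(ctg))
  expect_equal(length(lengthFilter(character(0), 200L)), 0L)
})

test_that("sample merging prefixes ids and rejects collisions", {
  s1 <- c(Locus_1 = "ACGT")
  s2 <- c(Locus_1 = "TTTT")
  out <- mergeSamples(list(gill = s1, mantle = s2))
  expect_equal(names(out), c("gill|Locus_1", "mantle|Locus_1"))
  expect_error(mergeSamples(list(gill = s1, gill = s2)), "duplicate sample")
})
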