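# N-based read cleansing and digital normalization.

test_that("longest N-free interval picks the maximal run, leftmost on ties", {
  expect_equal(longestNFreeInterval("ACGTNACGTACG"), c(5L, 12L))
  expect_equal(longestNFreeInterval("ACGTACGT"), c(0L, 8L))
  expect_equal(longestNFreeInterval("ACNGTNAC"), c(0L, 2L))  # three 2-runs
  expect_equal(longestNFreeInterval("NNNN"), c(0L, 0L))
  expect_equal(longestNFreeInterval(""), c(0L, 0L))
})

test_that("the half-length boundary removes, strict majority trims", {
  mk <- function(run, L) paste0(strrep("A", run), strrep("N", L - run))
  # run of exactly half -> removed; half + 1 -> trimmed
  r50 <- cleanseRead("x", mk(50L, 100L), strrep("I", 100L))
  expect_equal(r50$action, "discarded")
  r51 <- cleanseRead("x", mk(51L, 100L), strrep("I", 100L))
  expect_equal(r51$action, "trimmed")
  expect_equal(nchar(r51$bases), 51L)
  expect_equal(nchar(r51$quals), 51L)
  # odd length: 2*4 > 7 keeps, no integer truncation
  expect_equal(cleanseRead("x", mk(4L, 7L), strrep("I", 7L))$action,
               "trimmed")
  # keepAtHalf flips the boundary only
  expect_equal(cleanseRead("x", mk(50L, 100L), strrep("I", 100L),
                           keepAtHalf = TRUE)$action, "trimmed")
  expect_equal(cleanseRead("x", mk(49L, 100L), strrep("I", 100L),
                           keepAtHalf = TRUE)$action, "discarded")
})

test_that("cleansing is idempotent and outputs never contain N", {
  set.seed(5)
  reads <- data.frame(
    id = sprintf("r%02d", 1:40),
    bases = vapply(1:40, function(i) {
      s <- randSeq(60)
      nPos <- sample.int(60, sample(0:40, 1))
      if (length(nPos)) {
        ch <- strsplit(s, "")[[1]]; ch[nPos] <- "N"; s <- paste(ch, collapse = "")
      }
      s
    }, character(1)), stringsAsFactors = FALSE)
  reads$quals <- strrep("I", 60)
  out <- cleanseReads(reads)
  expect_false(any(grepl("N", out$reads$bases, fixed = TRUE)))
  expect_true(all(2L * nchar(out$reads$bases) > 60L))
  again <- cleanseReads(out$reads)
  expect_identical(again$reads, out$reads)
  expect_equal(unname(again$report["discarded_self"]), 0L)
  expect_equal(unname(out$report["input"]), 40L)
})

test_that("a discarded mate removes both reads of the pair", {
  r1 <- data.frame(id = c("p1/1", "p2/1", "p3/1"),
                   bases = c(randSeq(50), randSeq(50), randSeq(50)),
                   quals = strrep("I", 50), stringsAsFactors = FALSE)
  r2 <- r1
  r2$id <- sub("/1", "/2", r2$id)
  r2$bases[2L] <- strrep("N", 50)  # all-N mate
  out <- cleanseReads(r1, r2)
  expect_equal(out$reads$id, c("p1/1", "p3/1"))
  expect_equal(out$reads2$id, c("p1/2", "p3/2"))
  expect_equal(unname(out$report["discarded_by_mate"]), 1L)
  expect_equal(unname(out$report["discarded_self"]), 1L)
  # matching ids after suffix stripping is enforced
  r2bad <- r2; r2bad$id[1L] <- "zz/2"
  expect_error(cleanseReads(r1, r2bad), "desynchronized")
})

test_that("digital normalization caps identical reads at maxCoverage + 1", {
  set.seed(8)
  base <- randSeq(30)  # non-periodic: every 11-mer window distinct
  stopifnot(!anyDuplicated(substring(base, 1:20, 11:30)))
  rd <- data.frame(id = sprintf("r%03d", 1:100), bases = base,
                   quals = strrep("I", 30), stringsAsFactors = FALSE)
  out <- kmerNormalize(rd, k = 11L, maxCoverage = 20L)
  # read i sees median coverage i-1; accepted while i-1 <= 20
  expect_equal(nrow(out$reads), 21L)
  expect_true(nrow(out$reads) <= 21L)
  # exact re-count oracle: k-mer counts over kept reads
  km <- unlist(lapply(out$reads$bases, function(b) {
    st <- 1:(nchar(b) - 10L)
    substring(b, st, st + 10L)
  }))
  expect_true(all(table(km) <= 21L))
})

test_that("distinct reads pass normalization untouched and bad parameters fail", {
  set.seed(3)
  rd <- data.frame(id = sprintf("r%02d", 1:30),
                   bases = vapply(1:30, function(i) randSeq(40), character(1)),
                   quals = strrep("I", 40), stringsAsFactors = FALSE)
  out <- kmerNormalize(rd, k = 25L, maxCoverage = 30L)
  expect_equal(nrow(out$reads), 30L)
  # reads shorter than k kept unconditionally
  short <- data.frame(id = "s", bases = "ACGT", quals = "IIII")
  expect_equal(unname(kmerNormalize(short, k = 11L)$report["too_short"]), 1L)
  expect_error(kmerNormalize(rd, k = 25L, maxCoverage = 0L))
  expect_error(kmerNormalize(rd, k = 24L))  # even k rejected
})
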