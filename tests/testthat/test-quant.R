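# Contig indel correction, RPM filtering, count matrix.

test_that("a planted spurious base is removed and correction then converges", {
  set.seed(91)
  true <- randSeq(60)
  # assembly inserted a spurious base at 0-based position 30
  contig <- paste0(substr(true, 1, 30), "A", substr(true, 31, 60))
  # reads = exact substrings of the truth, aligned with a 1D at that column
  alnRows <- lapply(1:10, function(i) {
    start <- 10L  # 0-based on contig; spans the spurious base
    data.frame(readId = paste0("r", i), contigId = "c", pos = start,
               strand = "+", cigar = "20M1D20M", mapq = 60L, nm = 1L,
               seq = substr(true, start + 1L, start + 40L),
               stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, alnRows)
  ctg <- c(c = contig)
  pil <- buildPileup(aln, ctg)
  res <- correctContig(contig, pil$c)
  expect_equal(res$seq, true)
  expect_equal(res$edits$type, "del_base")
  expect_equal(res$edits$pos, 30L)
  # second pass with consistent alignments makes no further edits
  aln2 <- aln; aln2$cigar <- "40M"
  pil2 <- buildPileup(aln2, c(c = res$seq))
  res2 <- correctContig(res$seq, pil2$c)
  expect_equal(nrow(res2$edits), 0L)
  expect_equal(res2$seq, true)
})

test_that("a majority-supported insertion is restored and the depth gate holds", {
  set.seed(92)
  true <- randSeq(50)
  # assembly dropped the base at 0-based position 25
  contig <- paste0(substr(true, 1, 25), substr(true, 27, 50))
  ins <- substr(true, 26, 26)
  aln <- do.call(rbind, lapply(1:6, function(i) data.frame(
    readId = paste0("r", i), contigId = "c", pos = 5L, strand = "+",
    cigar = paste0("20M1I15M"), mapq = 60L, nm = 1L,
    seq = substr(true, 6L, 41L), stringsAsFactors = FALSE)))
  pil <- buildPileup(aln, c(c = contig))
  res <- correctContig(contig, pil$c)
  expect_equal(res$seq, true)
  expect_equal(res$edits$type, "ins_seq")
  expect_equal(res$edits$detail, ins)

  # depth 3 with unanimous signal stays uncorrected at minDepth 4
  pil3 <- buildPileup(aln[1:3, ], c(c = contig))
  res3 <- correctContig(contig, pil3$c, minDepth = 4L)
  expect_equal(res3$seq, contig)
  expect_equal(nrow(res3$edits), 0L)
})

test_that("clean contigs with agreeing reads receive zero edits", {
  set.seed(93)
  ctg <- c(c = randSeq(120))
  reads <- data.frame(id = sprintf("r%d", 1:20),
                      bases = vapply(1:20, function(i) {
                        st <- sample.int(40, 1L)
                        substr(ctg[["c"]], st, st + 79L)
                      }, character(1)),
                      quals = strrep("I", 80L), stringsAsFactors = FALSE)
  aln <- mapReads(reads, ctg)
  res <- correctContigs(ctg, buildPileup(aln, ctg))
  expect_equal(res$contigs, ctg)
  expect_equal(nrow(res$edits), 0L)
})

test_that("RPM boundaries are inclusive at the threshold and the filter is monotone", {
  expect_false(rpmFilter(1L, 1e6))   # 1 RPM -> excluded
  expect_true(rpmFilter(2L, 1e6))    # exactly 2 RPM -> kept
  expect_false(rpmFilter(0L, 100L))
  expect_error(rpmFilter(5L, 0L))
  # monotone in count, antitone in total
  counts <- 0:50
  keep <- rpmFilter(counts, 1e6, threshold = 2)
  expect_true(all(diff(keep) >= 0))
  totals <- c(1e5, 1e6, 1e7)
  keepT <- vapply(totals, function(t) rpmFilter(3L, t), logical(1))
  expect_true(all(diff(keepT) <= 0))
})

test_that("the count matrix reproduces planted counts and conserves reads", {
  mkAln <- function(n, contig, lib) {
    if (n == 0L) return(data.frame(readId = character(0),
                                   contigId = character(0)))
    data.frame(readId = sprintf("%s_%s_%d", lib, contig, 1:n),
               contigId = contig, stringsAsFactors = FALSE)
  }
  libA <- rbind(mkAln(10L, "c1", "A"), mkAln(3L, "c2", "A"))
  libB <- rbind(mkAln(0L, "c1", "B"), mkAln(7L, "c2", "B"))
  cm <- buildCountMatrix(list(A = libA, B = libB), c("c1", "c2"),
                         c(A = 100, B = 100))
  cts <- SummarizedExperiment::assay(cm, "counts")
  expect_equal(unname(cts), matrix(c(10L, 3L, 0L, 7L), ncol = 2L))
  expect_equal(sum(cts), nrow(libA) + nrow(libB))  # conservation
  # zero column for a library with no mapped reads
  cmZ <- buildCountMatrix(list(A = libA, Z = mkAln(0L, "c1", "Z")),
                          c("c1", "c2"), c(A = 100, Z = 50))
  expect_equal(unname(SummarizedExperiment::assay(cmZ)[, "Z"]), c(0L, 0L))
  # foreign contig universe is rejected
  expect_error(buildCountMatrix(list(A = libA), c("c1"), c(A = 100)),
               "universe")
  # ContigCounts validity: totals must bound column sums
  expect_error(ContigCounts(matrix(5L, 1, 1, dimnames = list("c", "l")),
                            c(l = 2)), "exceed")
})
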