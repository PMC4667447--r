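# Exact-seed read mapping and pileup construction.

test_that("exact substrings map to their true position on both strands", {
  set.seed(81)
  ctg <- c(C = randSeq(400))
  read <- substr(ctg[["C"]], 38L, 137L)  # 0-based offset 37, 100 bp
  reads <- data.frame(id = c("f", "r"),
                      bases = c(read, rcOracle(read)),
                      quals = strrep("I", 100L), stringsAsFactors = FALSE)
  aln <- mapReads(reads, ctg)
  expect_equal(aln$pos, c(37L, 37L))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$cigar, c("100M", "100M"))
  expect_equal(aln$nm, c(0L, 0L))
  expect_equal(aln$mapq, c(60L, 60L))
  # the minus-strand SEQ is stored in contig orientation
  expect_equal(aln$seq[2L], read)
})

test_that("reads within the mismatch budget always map to their origin", {
  set.seed(82)
  tx <- makeTranscriptome(5L, seed = 82L)
  sim <- makeReads(tx$transcripts, depth = 5, readLen = 80L,
                   errorRate = 0.01, seed = 82L)
  aln <- mapReads(sim$reads, tx$transcripts)
  truth <- sim$truth
  m <- match(truth$readId, aln$readId)
  # deterministic guarantee: every read with <= budget realized errors maps,
  # and maps exactly at its origin (transcripts are mutually unrelated)
  budget <- floor(0.04 * 80)
  origin <- vapply(seq_len(nrow(truth)), function(i)
    substr(tx$transcripts[[truth$transcript[i]]], truth$start[i] + 1L,
           truth$start[i] + 80L), character(1))
  errs <- vapply(seq_len(nrow(truth)), function(i)
    sum(strsplit(sim$reads$bases[i], "")[[1L]] !=
        strsplit(origin[i], "")[[1L]]), integer(1))
  inBudget <- errs <= budget
  expect_true(all(!is.na(m[inBudget])))
  mapped <- m[inBudget]
  expect_true(all(aln$contigId[mapped] == truth$transcript[inBudget]))
  expect_true(all(aln$pos[mapped] == truth$start[inBudget]))
  expect_true(all(aln$nm[mapped] == errs[inBudget]))
  expect_gt(mean(!is.na(m)), 0.98)
})

test_that("pileup tallies bases, honours the mapq threshold and the depth cap", {
  ctg <- c(c1 = strrep("A", 30L))
  mk <- function(id, seq, mapq) data.frame(
    readId = id, contigId = "c1", pos = 0L, strand = "+",
    cigar = paste0(nchar(seq), "M"), mapq = mapq, nm = 0L, seq = seq,
    stringsAsFactors = FALSE)
  aln <- rbind(mk("r1", strrep("A", 10L), 60L),
               mk("r2", strrep("A", 10L), 60L),
               mk("r3", strrep("A", 10L), 60L),
               mk("r4", paste0("G", strrep("A", 9L)), 60L),
               mk("r5", paste0("G", strrep("A", 9L)), 60L),
               mk("lowq", strrep("C", 10L), 29L))
  pil <- buildPileup(aln, ctg)
  col0 <- pileupColumn(pil, "c1", 0L)
  expect_equal(unname(col0$baseCounts["A"]), 3L)
  expect_equal(unname(col0$baseCounts["G"]), 2L)
  expect_equal(unname(col0$baseCounts["C"]), 0L)  # mapq 29 contributes nothing
  expect_equal(col0$depth, 5L)

  # depth cap: the 6th read at maxDepth = 5 is ignored
  aln2 <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("d", i), strrep("A", 10L), 60L)))
  pil2 <- buildPileup(aln2, ctg, maxDepth = 5L)
  expect_equal(pileupColumn(pil2, "c1", 3L)$depth, 5L)
})

test_that("gapped CIGARs produce anchored insertion and deletion events", {
  ctg <- c(c1 = "ACGTACGTACGTACGTACGT")
  # 3 reads with a deletion of ref positions 5..6 (anchor at 4)
  alnD <- do.call(rbind, lapply(1:3, function(i) data.frame(
    readId = paste0("d", i), contigId = "c1", pos = 0L, strand = "+",
    cigar = "5M2D5M", mapq = 60L, nm = 2L,
    seq = paste0(substr(ctg, 1, 5), substr(ctg, 8, 12)),
    stringsAsFactors = FALSE)))
  pil <- buildPileup(alnD, ctg)
  col <- pileupColumn(pil, "c1", 4L)
  expect_equal(unname(col$events["4|D|CG"]), 3L)
  expect_equal(pileupColumn(pil, "c1", 5L)$del, 3L)
  # 2 reads with insertion GT after ref position 10 (anchor 10)
  alnI <- do.call(rbind, lapply(1:2, function(i) data.frame(
    readId = paste0("i", i), contigId = "c1", pos = 0L, strand = "+",
    cigar = "11M2I9M", mapq = 60L, nm = 2L,
    seq = paste0(substr(ctg, 1, 11), "GT", substr(ctg, 12, 20)),
    stringsAsFactors = FALSE)))
  pilI <- buildPileup(alnI, ctg)
  expect_equal(unname(pileupColumn(pilI, "c1", 10L)$events["10|I|GT"]), 2L)
})
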