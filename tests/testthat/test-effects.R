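# Transcript-coordinate effect classification and summary tables.

test_that("every possible SNP on the worked toy contig matches the hand-derived truth", {
  gm <- toyModel()
  chars <- strsplit(toyContig, "")[[1L]]
  cdsCats <- c("synonymous_variant", "missense_variant", "stop_gained",
               "stop_lost", "stop_retained_variant", "start_lost",
               "initiator_codon_variant")
  for (pos in 0:12) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos + 1L])) {
      got <- classifyEffect(mkVar("toy", pos, chars[pos + 1L], alt),
                            gm, toyContig)
      expect_equal(got$categories, toySnpTruth(pos, alt),
                   info = sprintf("pos %d %s>%s", pos, chars[pos + 1L], alt))
      # single-region SNPs carry exactly one category, and CDS SNP
      # categories partition into exactly one coding class
      expect_length(got$categories, 1L)
      if (pos >= 2L && pos <= 10L) {
        expect_true(got$categories %in% cdsCats)
        expect_length(got$codonChange, 2L)
      }
    }
  }
})

test_that("contigs without a gene model give intergenic calls and bad coordinates error", {
  got <- classifyEffect(mkVar("c", 3L, "A", "G"), NULL, "ACGTACGT")
  expect_equal(got$categories, "intergenic_region")
  expect_error(classifyEffect(mkVar("c", 50L, "A", "G"), NULL, "ACGT"),
               "outside")
})

test_that("CDS indels are classified by length, codon alignment and touched codons", {
  gm <- toyModel()
  cl <- function(pos, ref, alt, vtype)
    sort(classifyEffect(mkVar("toy", pos, ref, alt, vtype = vtype),
                        gm, toyContig)$categories)
  # 3 bp codon-aligned deletion of the AAA codon
  expect_equal(cl(4L, "GAAA", "G", "DEL"), "inframe_deletion")
  # 1 bp deletion in CDS
  expect_equal(cl(4L, "GA", "G", "DEL"), "frameshift_variant")
  # 3 bp deletion not codon-aligned
  expect_equal(cl(5L, "AAAT", "A", "DEL"),
               c("disruptive_inframe_deletion", "stop_lost"))
  # codon-aligned insertion of one codon; TAA insert creates a stop
  expect_equal(cl(4L, "G", "GTTT", "INS"), "inframe_insertion")
  expect_equal(cl(4L, "G", "GTAA", "INS"),
               c("inframe_insertion", "stop_gained"))
  # deletion spanning the 5'UTR/CDS boundary destroys the initiator
  expect_equal(cl(1L, "CATG", "C", "DEL"),
               c("inframe_deletion", "start_lost"))
  # deletion of the whole CDS
  expect_equal(cl(1L, "CATGAAATAG", "C", "DEL"),
               "chromosome_number_variation")
  # UTR-only indel
  expect_equal(cl(11L, "C", "CG", "INS"), "3_prime_UTR_variant")
  # all emitted categories stay within the controlled vocabulary
  all3 <- c(cl(4L, "GAAA", "G", "DEL"), cl(4L, "G", "GTAA", "INS"),
            cl(1L, "CATG", "C", "DEL"))
  expect_true(all(all3 %in% effectVocabulary))
})

test_that("minus-strand gene models classify through the reverse complement", {
  rcContig <- rcOracle(toyContig)   # GGCTATTTCATGG
  orf <- findLongestOrf(rcContig, minLenNt = 9L)
  expect_equal(orf$strand, "-")
  gm <- geneModelFromOrf("rc", 13L, orf)
  chars <- strsplit(rcContig, "")[[1L]]
  # forward-strand position p on the rc contig mirrors 12 - p on the toy
  for (pos in 0:12) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos + 1L])) {
      got <- classifyEffect(mkVar("rc", pos, chars[pos + 1L], alt), gm,
                            rcContig)
      mirroredAlt <- rcOracle(alt)
      expect_equal(got$categories, toySnpTruth(12L - pos, mirroredAlt),
                   info = sprintf("rc pos %d >%s", pos, alt))
    }
  }
})

test_that("alternative start codons turn start_lost into initiator_codon_variant", {
  gm <- toyModel()
  v <- mkVar("toy", 2L, "A", "T")  # ATG -> TTG
  expect_equal(classifyEffect(v, gm, toyContig)$categories, "start_lost")
  expect_equal(classifyEffect(v, gm, toyContig,
                              altStartCodons = c("TTG", "CTG", "GTG"))$categories,
               "initiator_codon_variant")
})

test_that("summaries join multi-category combos and report 3-decimal percentages", {
  anns <- c(rep(list(list(categories = "synonymous_variant")), 3L),
            list(list(categories = "missense_variant")),
            list(list(categories = c("frameshift_variant", "stop_gained"))),
            list(list(categories = c("stop_gained", "frameshift_variant"))))
  tab <- summarizeEffects(anns)
  expect_equal(tab$type, c("frameshift_variant + stop_gained",
                           "missense_variant", "synonymous_variant"))
  expect_equal(tab$count, c(2L, 1L, 3L))
  expect_equal(tab$percent, c(33.333, 16.667, 50))
  expect_equal(nrow(summarizeEffects(list())), 0L)
})
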