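# Library pooling, Fisher exact DDD, multiple-testing control, Venn regions.

makeCounts <- function(mat, totals) {
  ContigCounts(mat, totals)
}

test_that("pooling sums counts and totals, and rejects bad groupings", {
  cts <- matrix(c(10L, 0L, 3L, 7L, 2L, 2L), nrow = 2L, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("l1", "l2", "l3")))
  cm <- makeCounts(cts, c(l1 = 100, l2 = 200, l3 = 300))
  pools <- poolLibraries(cm, list(A = c("l1", "l2"), B = "l3"))
  expect_equal(unname(pools$A$pooledCounts), c(10L, 9L))
  expect_equal(pools$A$pooledTotal, 300)
  expect_equal(unname(pools$B$pooledCounts), c(3L, 2L))
  expect_equal(pools$B$pooledTotal, 300)
  expect_error(poolLibraries(cm, list(A = "l1", B = c("l1", "l2"))),
               "disjoint")
  expect_error(poolLibraries(cm, list(A = "nope")), "unknown")
})

test_that("the two-sided Fisher p matches enumeration and honours symmetries", {
  expect_identical(fisherExactTwoSided(1, 0, 0, 1), 1.0)
  expect_equal(fisherExactTwoSided(5, 95, 5, 95), 1.0)
  expect_equal(fisherExactTwoSided(2, 8, 8, 2), fisherOracle(2, 8, 8, 2),
               tolerance = 1e-12)
  # row and column swaps leave p unchanged
  set.seed(101)
  for (i in 1:50) {
    x <- sample(0:30, 4L, TRUE)
    p <- fisherExactTwoSided(x[1], x[2], x[3], x[4])
    expect_equal(fisherExactTwoSided(x[3], x[4], x[1], x[2]), p,
                 tolerance = 1e-12)
    expect_equal(fisherExactTwoSided(x[2], x[1], x[4], x[3]), p,
                 tolerance = 1e-12)
    expect_equal(p, fisherOracle(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-10)
    # reference implementation agrees
    ft <- stats::fisher.test(matrix(x, 2L, byrow = TRUE))$p.value
    expect_equal(p, ft, tolerance = 1e-7)
  }
  expect_identical(fisherExactTwoSided(0, 0, 5, 5), 1.0)  # zero margin
})

test_that("DDD ranks a strongly enriched contig first and is invariant to library order", {
  set.seed(102)
  n <- 40L
  base <- sample(20:60, n, TRUE)
  cts <- cbind(a1 = base, a2 = base,
               b1 = base + sample(-3:3, n, TRUE), b2 = base)
  rownames(cts) <- sprintf("c%02d", 1:n)
  cts["c05", ] <- c(400L, 420L, 40L, 38L)  # ~10x rate in pool A
  cm <- makeCounts(cts, c(a1 = 5000, a2 = 5000, b1 = 5000, b2 = 5000))
  res <- runDdd(cm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$contigId[1L], "c05")
  expect_equal(res$direction[1L], "up_in_a")
  # permuting library order within pools changes nothing
  res2 <- runDdd(cm, c("a2", "a1"), c("b2", "b1"))
  expect_equal(res2$p, res$p)
  expect_equal(res2$q, res$q)
  # zero-vs-zero contig gets p = 1, direction none
  cts0 <- rbind(cts, c00 = c(0L, 0L, 0L, 0L))
  cm0 <- makeCounts(cts0, c(a1 = 5000, a2 = 5000, b1 = 5000, b2 = 5000))
  res0 <- runDdd(cm0, c("a1", "a2"), c("b1", "b2"))
  r <- res0[res0$contigId == "c00", ]
  expect_equal(r$p, 1.0)
  expect_equal(r$direction, "none")
})

test_that("BH q-values match the step-up definition", {
  set.seed(103)
  p <- c(runif(30), runif(10, 0, 1e-3))
  q <- stats::p.adjust(p, "BH")
  # brute-force BH: q_(i) = min_{j >= i} p_(j) * n / j
  ord <- order(p)
  n <- length(p)
  qo <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  expect_equal(q[ord], pmin(qo, 1))
  # rejections at alpha match the classic definition
  alpha <- 0.05
  k <- max(c(0L, which(p[ord] <= seq_len(n) / n * alpha)))
  rejected <- if (k > 0L) ord[seq_len(k)] else integer(0)
  expect_setequal(which(q <= alpha), rejected)
})

test_that("Venn signatures partition present contigs into regions", {
  cts <- matrix(c(5L, 0L, 2L,
                  0L, 4L, 1L,
                  0L, 0L, 0L,
                  3L, 3L, 3L), nrow = 4L, byrow = TRUE,
                dimnames = list(sprintf("c%d", 1:4), c("x", "y", "z")))
  cm <- makeCounts(cts, c(x = 100, y = 100, z = 100))
  vr <- vennRegions(cm, list(X = "x", Y = "y", Z = "z"))
  sig <- setNames(vr$signatures$signature, vr$signatures$contigId)
  expect_equal(unname(sig["c1"]), "X&Z")
  expect_equal(unname(sig["c2"]), "Y&Z")
  expect_equal(unname(sig["c3"]), "")       # present nowhere, listed
  expect_equal(unname(sig["c4"]), "X&Y&Z")
  expect_equal(sum(vr$regions), 3L)         # non-empty signatures only
  expect_error(vennRegions(cm, list(A = "x")), "2 to 4")
  # RPM presence rule
  vr2 <- vennRegions(cm, list(X = "x", Y = "y"), minRpm = 40000)
  expect_equal(vr2$signatures$signature[1L], "X")
})
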