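# Library pooling, Fisher's exact test digital differential display (DDD)
# between pools, multiple-testing control, and presence/absence Venn
# region assignment.

#' Pool libraries of a count matrix
#'
#' @param counts A \linkS4class{ContigCounts}.
#' @param grouping Named list: pool name -> character vector of library
#'   ids. Libraries must exist and pools must be disjoint.
#' @return Named list of pools; each pool has `name`, `libraryIds`,
#'   `pooledCounts` (named per-contig row sums) and `pooledTotal`.
#' @export
poolLibraries <- function(counts, grouping) {
  stopifnot(methods::is(counts, "ContigCounts"), length(grouping) >= 1L)
  allLibs <- unlist(grouping, use.names = FALSE)
  unknown <- setdiff(allLibs, colnames(counts))
  if (length(unknown))
    stop("unknown library id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(allLibs))
    stop("pools must be disjoint")
  cts <- SummarizedExperiment::assay(counts, "counts")
  tot <- libraryTotals(counts)
  lapply(stats::setNames(names(grouping), names(grouping)), function(nm) {
    libs <- grouping[[nm]]
    list(name = nm, libraryIds = libs,
         pooledCounts = rowSums(cts[, libs, drop = FALSE]),
         pooledTotal = sum(tot[libs]))
  })
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration of the hypergeometric
#' support at fixed margins, summing the probabilities of all tables whose
#' probability does not exceed that of the observed table (with a
#' `1 + 1e-7` relative tolerance on the comparison to absorb
#' floating-point ties). Probabilities are computed in log space from
#' cumulative log-factorials. A table with an all-zero margin returns 1 by
#' convention.
#'
#' @param a,b,c,d Non-negative integer cell counts of the table
#'   `[[a, b], [c, d]]`.
#' @return The two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' fisherExactTwoSided(1, 0, 0, 1)  # 1
fisherExactTwoSided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c1 == n) return(1.0)
  lfact <- cumsum(c(0, log(seq_len(n))))  # lfact[k+1] = log(k!)
  lf <- function(k) lfact[k + 1L]
  logp <- function(x) {
    lf(r1) - lf(x) - lf(r1 - x) +
      lf(r2) - lf(c1 - x) - lf(r2 - c1 + x) +
      lf(n - c1) + lf(c1) - lf(n)
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  lp <- vapply(support, logp, numeric(1))
  pObs <- exp(logp(a))
  sum(exp(lp)[exp(lp) <= pObs * (1 + 1e-7)])
}

#' Digital differential display between two library pools
#'
#' For each contig, builds the 2x2 table `[[count_a, total_a - count_a],
#' [count_b, total_b - count_b]]`, computes the two-sided Fisher exact
#' p-value, and controls multiple testing over all tested contigs
#' (Benjamini-Hochberg by default). Direction compares the pooled rates
#' `count/total`.
#'
#' @param counts A \linkS4class{ContigCounts}.
#' @param poolA,poolB Character vectors of library ids, or pool objects
#'   from [poolLibraries()].
#' @param mtMethod `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return data.frame sorted by `q`, then `p`, then `contigId`: columns
#'   `contigId`, `countA`, `countB`, `totalA`, `totalB`, `p`, `q`,
#'   `direction` (`up_in_a` / `up_in_b` / `none`).
#' @export
runDdd <- function(counts, poolA, poolB, mtMethod = c("BH", "bonferroni",
                                                      "none")) {
  mtMethod <- match.arg(mtMethod)
  asPool <- function(x, nm) {
    if (is.list(x) && !is.null(x$pooledCounts)) x
    else poolLibraries(counts, stats::setNames(list(x), nm))[[1L]]
  }
  pa <- asPool(poolA, "A"); pb <- asPool(poolB, "B")
  ids <- rownames(counts)
  p <- vapply(seq_along(ids), function(i) {
    fisherExactTwoSided(pa$pooledCounts[i], pa$pooledTotal - pa$pooledCounts[i],
                        pb$pooledCounts[i], pb$pooledTotal - pb$pooledCounts[i])
  }, numeric(1))
  q <- switch(mtMethod,
              BH = stats::p.adjust(p, "BH"),
              bonferroni = stats::p.adjust(p, "bonferroni"),
              none = p)
  rateA <- pa$pooledCounts / pa$pooledTotal
  rateB <- pb$pooledCounts / pb$pooledTotal
  direction <- ifelse(rateA > rateB, "up_in_a",
                      ifelse(rateB > rateA, "up_in_b", "none"))
  out <- data.frame(contigId = ids,
                    countA = as.integer(pa$pooledCounts),
                    countB = as.integer(pb$pooledCounts),
                    totalA = pa$pooledTotal, totalB = pb$pooledTotal,
                    p = p, q = q, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[cOrder(out$q, out$p, out$contigId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Presence/absence Venn region assignment over library pools
#'
#' Each contig is assigned the subset of pools in which it is "present"
#' (pooled count at or above `minCount`, or pooled RPM at or above
#' `minRpm` when given). Supports 2 to 4 pools.
#'
#' @param counts A \linkS4class{ContigCounts}.
#' @param grouping Named list of pools (see [poolLibraries()]).
#' @param minCount Presence rule: pooled count threshold. Default 1.
#' @param minRpm Optional presence rule: pooled RPM threshold; overrides
#'   `minCount` when non-`NULL`.
#' @return List with `signatures` (data.frame `contigId`, `signature` —
#'   pool names joined by `"&"`, empty string when present nowhere) and
#'   `regions` (named region tallies over non-empty signatures).
#' @export
vennRegions <- function(counts, grouping, minCount = 1L, minRpm = NULL) {
  if (length(grouping) < 2L || length(grouping) > 4L)
    stop("vennRegions supports 2 to 4 pools")
  pools <- poolLibraries(counts, grouping)
  present <- vapply(pools, function(p) {
    if (!is.null(minRpm)) p$pooledCounts / p$pooledTotal * 1e6 >= minRpm
    else p$pooledCounts >= minCount
  }, logical(nrow(counts)))
  if (nrow(counts) == 1L) present <- matrix(present, nrow = 1L)
  sig <- apply(present, 1L, function(r)
    paste(names(grouping)[r], collapse = "&"))
  signatures <- data.frame(contigId = rownames(counts), signature = sig,
                           stringsAsFactors = FALSE)
  nonEmpty <- sig[nzchar(sig)]
  regions <- if (length(nonEmpty)) table(nonEmpty) else table(character(0))
  list(signatures = signatures,
       regions = stats::setNames(as.integer(regions), names(regions)))
}
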