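# Read cleansing: keep the longest N-free sub-sequence of each read, drop
# reads whose longest N-free run does not exceed half the read length (and
# their mates), and optionally downsample over-represented reads by median
# canonical k-mer coverage (digital normalization).

#' Longest N-free interval of a base string
#'
#' Returns the maximal-length run containing no `N`, as a 0-based half-open
#' interval. Ties between equal-length runs are broken by the leftmost
#' start; an all-`N` (or empty) string yields the empty interval `[0, 0)`.
#'
#' @param bases A single base string over `{A,C,G,T,N}`.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
#' @examples
#' longestNFreeInterval("ACGTNACGTACG")  # c(5, 12)
longestNFreeInterval <- function(bases) {
  stopifnot(length(bases) == 1L)
  n <- nchar(bases)
  if (n == 0L) return(c(0L, 0L))
  isN <- strsplit(bases, "", fixed = TRUE)[[1L]] == "N"
  if (all(isN)) return(c(0L, 0L))
  r <- rle(isN)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  free <- which(!r$values)
  best <- free[which.max(r$lengths[free])]  # which.max -> leftmost tie-break
  c(starts[best] - 1L, ends[best])
}

#' Cleanse a single read
#'
#' Applies the N-based rule: extract the longest N-free sub-sequence; if its
#' length does not exceed half of the read length the read is discarded
#' (boundary `2 * L_sub == L` is removal; comparison is `2 * L_sub <= L` in
#' exact integer arithmetic, so odd lengths need no rounding convention).
#' Qualities are trimmed in sync with the bases.
#'
#' @param id,bases,quals Read fields.
#' @param keepAtHalf If `TRUE`, a run of exactly half the read length is
#'   kept (trimmed) instead of discarded.
#' @return A list with `action` (`"kept_full"`, `"trimmed"` or
#'   `"discarded"`), `interval` (0-based half-open, `NULL` when discarded)
#'   and, unless discarded, the trimmed `id`, `bases`, `quals`.
#' @export
cleanseRead <- function(id, bases, quals, keepAtHalf = FALSE) {
  iv <- longestNFreeInterval(bases)
  L <- nchar(bases)
  Lsub <- iv[2L] - iv[1L]
  removed <- if (keepAtHalf) 2L * Lsub < L else 2L * Lsub <= L
  if (L == 0L || removed)
    return(list(action = "discarded", interval = NULL))
  if (Lsub == L)
    return(list(action = "kept_full", interval = iv,
                id = id, bases = bases, quals = quals))
  list(action = "trimmed", interval = iv, id = id,
       bases = substr(bases, iv[1L] + 1L, iv[2L]),
       quals = substr(quals, iv[1L] + 1L, iv[2L]))
}

stripMateSuffix <- function(ids) sub("/[12]$", "", ids)

#' Cleanse a stream of reads, propagating discards to mates
#'
#' For single-end input each read is cleansed independently. For paired
#' input (`reads2` given) the files must be synchronized; when either mate
#' is discarded by the N rule, both are removed.
#'
#' @param reads Read table (data.frame `id`, `bases`, `quals`).
#' @param reads2 Optional mate read table of equal length.
#' @param keepAtHalf See [cleanseRead()].
#' @return A list with `reads` (and `reads2` for paired input) holding the
#'   kept, trimmed reads in input order, and `report`, a named integer
#'   vector counting `input`, `kept_full`, `trimmed`, `discarded_self`,
#'   `discarded_by_mate` (reads, not pairs).
#' @export
cleanseReads <- function(reads, reads2 = NULL, keepAtHalf = FALSE) {
  one <- function(rd) lapply(seq_len(nrow(rd)), function(i)
    cleanseRead(rd$id[i], rd$bases[i], rd$quals[i], keepAtHalf))
  collect <- function(rd, res, keep) {
    data.frame(
      id = vapply(res[keep], `[[`, character(1), "id"),
      bases = vapply(res[keep], `[[`, character(1), "bases"),
      quals = vapply(res[keep], `[[`, character(1), "quals"),
      stringsAsFactors = FALSE)
  }
  emptyReads <- data.frame(id = character(0), bases = character(0),
                           quals = character(0), stringsAsFactors = FALSE)
  if (is.null(reads2)) {
    res <- one(reads)
    act <- vapply(res, `[[`, character(1), "action")
    keep <- act != "discarded"
    out <- if (any(keep)) collect(reads, res, keep) else emptyReads
    report <- c(input = nrow(reads),
                kept_full = sum(act == "kept_full"),
                trimmed = sum(act == "trimmed"),
                discarded_self = sum(!keep),
                discarded_by_mate = 0L)
    return(list(reads = out, report = report))
  }
  if (nrow(reads) != nrow(reads2))
    stop("desynchronized mate files: unequal read counts")
  if (!all(stripMateSuffix(reads$id) == stripMateSuffix(reads2$id)))
    stop("desynchronized mate files: read id mismatch")
  r1 <- one(reads); r2 <- one(reads2)
  a1 <- vapply(r1, `[[`, character(1), "action")
  a2 <- vapply(r2, `[[`, character(1), "action")
  selfDrop1 <- a1 == "discarded"; selfDrop2 <- a2 == "discarded"
  keep <- !(selfDrop1 | selfDrop2)
  out1 <- if (any(keep)) collect(reads, r1, keep) else emptyReads
  out2 <- if (any(keep)) collect(reads2, r2, keep) else emptyReads
  report <- c(
    input = nrow(reads) + nrow(reads2),
    kept_full = sum(a1[keep] == "kept_full") + sum(a2[keep] == "kept_full"),
    trimmed = sum(a1[keep] == "trimmed") + sum(a2[keep] == "trimmed"),
    discarded_self = sum(selfDrop1) + sum(selfDrop2),
    discarded_by_mate = sum(!keep & !selfDrop1) + sum(!keep & !selfDrop2))
  list(reads = out1, reads2 = out2, report = report)
}

canonicalKmers <- function(bases, k) {
  L <- nchar(bases)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  fwd <- substring(bases, starts, starts + k - 1L)
  rev <- revComp(fwd)
  pmin(fwd, rev)
}

#' Digital normalization by median canonical k-mer coverage
#'
#' Streaming downsampling of over-represented reads: a read is discarded
#' when the median count of its canonical k-mers, tallied over the reads
#' accepted so far, already exceeds `maxCoverage`. Counting is exact (no
#' sketch), so the result is deterministic given the input order. Reads
#' shorter than `k` (and reads whose k-mers all contain `N`) are kept
#' unconditionally and counted in the report.
#'
#' @param reads Read table.
#' @param k Odd k-mer size, `>= 11`. Default 25.
#' @param maxCoverage Coverage ceiling, `>= 1`. Default 30.
#' @return List with `reads` (the kept reads, input order) and `report`
#'   (named counts `input`, `kept`, `discarded`, `too_short`).
#' @export
kmerNormalize <- function(reads, k = 25L, maxCoverage = 30L) {
  stopifnot(k >= 11L, k %% 2L == 1L, maxCoverage >= 1L)
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  keep <- logical(nrow(reads))
  tooShort <- 0L
  for (i in seq_len(nrow(reads))) {
    km <- canonicalKmers(reads$bases[i], k)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (!length(km)) {
      keep[i] <- TRUE
      tooShort <- tooShort + 1L
      next
    }
    cur <- vapply(km, function(x) {
      v <- counts[[x]]
      if (is.null(v)) 0L else v
    }, integer(1), USE.NAMES = FALSE)
    if (stats::median(cur) > maxCoverage) next
    keep[i] <- TRUE
    for (x in unique(km))
      counts[[x]] <- (counts[[x]] %||% 0L) + sum(km == x)
  }
  list(reads = reads[keep, , drop = FALSE],
       report = c(input = nrow(reads), kept = sum(keep),
                  discarded = sum(!keep), too_short = tooShort))
}
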