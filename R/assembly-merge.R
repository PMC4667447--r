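# First-pass merging of multi-k-mer assemblies: per-locus representative
# selection, antisense-chimera split/removal, minimum-length filtering and
# cross-sample renaming.

#' Select the representative transcript of an assembly locus
#'
#' Among alternative transcript assemblies of one locus, keeps the member
#' maximizing `(length, depth)` lexicographically (or `(depth, length)`
#' with `key = "depth,len"`); remaining ties go to the lowest transcript
#' index, then the lexicographically smallest id.
#'
#' @param members data.frame with columns `id`, `length`, `depth`
#'   (`NA` depth ranks lowest) and optionally `transcriptIndex`.
#' @param key `"len,depth"` (default) or `"depth,len"`.
#' @return The representative `id`.
#' @export
selectLocusRepresentative <- function(members, key = c("len,depth", "depth,len")) {
  key <- match.arg(key)
  stopifnot(nrow(members) >= 1L)
  depth <- ifelse(is.na(members$depth %||% NA), -Inf, members$depth)
  ti <- members$transcriptIndex %||% rep(NA_integer_, nrow(members))
  ti <- ifelse(is.na(ti), .Machine$integer.max, ti)
  ord <- if (key == "len,depth")
    cOrder(-members$length, -depth, ti, members$id)
  else
    cOrder(-depth, -members$length, ti, members$id)
  members$id[ord[1L]]
}

#' Per-locus representative selection over a whole assembly
#'
#' Groups contigs by `(sample, kmer, locus)` using parsed header metadata
#' and keeps one representative per locus; contigs without locus metadata
#' pass through unchanged.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param meta data.frame parallel to `contigs` with columns `id`, `locus`,
#'   `transcriptIndex` (e.g. from [parseOasesHeader()]); optional column
#'   `depth`.
#' @inheritParams selectLocusRepresentative
#' @return Named character vector of the kept contigs (input order).
#' @export
locusRepresentatives <- function(contigs, meta, key = c("len,depth", "depth,len")) {
  key <- match.arg(key)
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  stopifnot(all(meta$id %in% names(seqs)))
  meta$length <- nchar(seqs[meta$id])
  if (is.null(meta$depth)) meta$depth <- NA_real_
  noLocus <- is.na(meta$locus)
  keepIds <- meta$id[noLocus]
  if (any(!noLocus)) {
    byLocus <- split(meta[!noLocus, , drop = FALSE], meta$locus[!noLocus])
    reps <- vapply(byLocus, selectLocusRepresentative, character(1), key = key)
    keepIds <- c(keepIds, unname(reps))
  }
  seqs[names(seqs) %in% keepIds]
}

complementBase <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Detect an antisense chimera by reverse-complement self-matching
#'
#' Searches for two non-overlapping blocks of the contig such that one is
#' the reverse complement of the other (exact seed-and-extend match),
#' evidence that the assembler concatenated a sequence with the reverse
#' complement of (part of) a sequence. When the best such match reaches
#' `minMatch` bases, the contig is a chimera: it is split at the midpoint
#' between the two blocks' inner boundaries when both fragments reach
#' `minFragmentLen`, otherwise flagged for removal.
#'
#' @param seq A single contig sequence.
#' @param seedLen Exact seed length (`>= 11`). Default 12.
#' @param minMatch Minimum self-match block length to call a chimera
#'   (`>= seedLen`). Default 60.
#' @param minIdentity Minimum identity of the matched block; the exact
#'   extension used here reports 1.0. Default 0.95.
#' @param minFragmentLen Minimum fragment length to allow a split (reuses
#'   the pipeline's 200 bp contig floor). Default 200.
#' @return List with `action` (`"intact"`, `"split"`, `"removed"`),
#'   `junction` (0-based split position, `NA` unless a chimera) and
#'   `evidence` (block coordinates, match length and identity; `NULL` when
#'   intact).
#' @export
detectAntisenseChimera <- function(seq, seedLen = 12L, minMatch = 60L,
                                   minIdentity = 0.95,
                                   minFragmentLen = 200L) {
  stopifnot(seedLen >= 11L, minMatch >= seedLen)
  L <- nchar(seq)
  if (L < 2L * seedLen)
    return(list(action = "intact", junction = NA_integer_, evidence = NULL))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- unname(complementBase[ch])
  comp[is.na(comp)] <- "N"
  k <- seedLen
  nSeeds <- L - k + 1L
  starts <- seq_len(nSeeds)
  seeds <- substring(seq, starts, starts + k - 1L)
  index <- split(starts - 1L, seeds)           # 0-based seed starts
  rcSeeds <- revComp(seeds)
  best <- NULL
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (i0 in starts - 1L) {
    js <- index[[rcSeeds[i0 + 1L]]]
    if (is.null(js)) next
    js <- js[js >= i0 + k]
    for (j0 in js) {
      key <- paste0(i0, ":", j0)
      if (!is.null(seen[[key]])) next
      a1 <- i0; a2 <- i0 + k; b1 <- j0; b2 <- j0 + k
      # inward: right end of block A pairs with left end of block B
      while (b1 - a2 >= 2L && ch[a2 + 1L] == comp[b1]) {
        a2 <- a2 + 1L; b1 <- b1 - 1L
      }
      # outward: left end of A pairs with right end of B
      while (a1 >= 1L && b2 <= L - 1L && ch[a1] == comp[b2 + 1L]) {
        a1 <- a1 - 1L; b2 <- b2 + 1L
      }
      # mark all seed pairs inside this block as visited
      if (a2 - a1 > k)
        for (t in 0:(a2 - a1 - k))
          seen[[paste0(a1 + t, ":", b2 - k - t)]] <- TRUE
      blockLen <- a2 - a1
      if (is.null(best) || blockLen > best$matchLen)
        best <- list(aStart = a1, aEnd = a2, bStart = b1, bEnd = b2,
                     matchLen = blockLen, identity = 1.0)
    }
  }
  if (is.null(best) || best$matchLen < minMatch || best$identity < minIdentity)
    return(list(action = "intact", junction = NA_integer_, evidence = best))
  junction <- (best$aEnd + best$bStart) %/% 2L
  action <- if (junction >= minFragmentLen && L - junction >= minFragmentLen)
    "split" else "removed"
  list(action = action, junction = junction, evidence = best)
}

#' Split or remove antisense chimeras in a contig set
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @inheritParams detectAntisenseChimera
#' @return List with `contigs` (intact contigs plus split fragments, named
#'   `<id>:5p` / `<id>:3p`) and `report` (data.frame `contigId`, `action`,
#'   `junction`, `matchLen`).
#' @export
processChimeras <- function(contigs, seedLen = 12L, minMatch = 60L,
                            minIdentity = 0.95, minFragmentLen = 200L) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  out <- character(0)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    call <- detectAntisenseChimera(seqs[[i]], seedLen, minMatch,
                                   minIdentity, minFragmentLen)
    rows[[i]] <- data.frame(
      contigId = id, action = call$action, junction = call$junction,
      matchLen = if (is.null(call$evidence)) NA_integer_ else
        call$evidence$matchLen,
      stringsAsFactors = FALSE)
    if (call$action == "intact") {
      out[id] <- seqs[[i]]
    } else if (call$action == "split") {
      out[paste0(id, ":5p")] <- substr(seqs[[i]], 1L, call$junction)
      out[paste0(id, ":3p")] <- substr(seqs[[i]], call$junction + 1L,
                                       nchar(seqs[[i]]))
    }
  }
  list(contigs = out, report = do.call(rbind, rows))
}

#' Filter contigs on a minimum length
#'
#' Keeps contigs whose length is greater than or equal to `minLen`
#' (inclusive: a contig of exactly `minLen` bases is kept).
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param minLen Minimum length in base pairs (`>= 1`). Default 200.
#' @return Filtered contigs, same container type, with an attribute
#'   `report` = `c(input, kept, dropped)`.
#' @export
lengthFilter <- function(contigs, minLen = 200L) {
  stopifnot(minLen >= 1L)
  w <- if (methods::is(contigs, "DNAStringSet")) Biostrings::width(contigs)
       else nchar(contigs)
  out <- contigs[w >= minLen]
  attr(out, "report") <- c(input = length(contigs), kept = length(out),
                           dropped = length(contigs) - length(out))
  out
}

#' Merge per-sample contig sets with sample-prefixed ids
#'
#' @param perSampleSets Named list (names = unique sample labels) of named
#'   character vectors or `DNAStringSet`s.
#' @param sep Separator between sample label and original id. Default `"|"`.
#' @return Named character vector with ids `<sample>|<original_id>`.
#' @export
mergeSamples <- function(perSampleSets, sep = "|") {
  if (anyDuplicated(names(perSampleSets)))
    stop("duplicate sample labels")
  out <- character(0)
  for (s in names(perSampleSets)) {
    x <- perSampleSets[[s]]
    seqs <- if (methods::is(x, "DNAStringSet"))
      stats::setNames(as.character(x), names(x)) else x
    names(seqs) <- paste0(s, sep, names(seqs))
    out <- c(out, seqs)
  }
  if (anyDuplicated(names(out)))
    stop("duplicate contig ids after sample prefixing")
  out
}
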