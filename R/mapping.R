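# Built-in read-to-contig mapper (deterministic exact-seed + ungapped
# extension) and pileup construction. Externally produced SAM alignments
# (readSam) are accepted by the same pileup code, including gapped CIGARs.

buildSeedIndex <- function(seqs, k) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[[ci]])
    if (L < k) next
    st <- seq_len(L - k + 1L)
    words <- substring(seqs[[ci]], st, st + k - 1L)
    for (t in seq_along(words)) {
      w <- words[t]
      env[[w]] <- rbind(env[[w]], c(ci, st[t] - 1L))
    }
  }
  env
}

countMismatches <- function(a, b) {
  # equal-length strings
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Map reads to contigs by exact seeding and ungapped extension
#'
#' Each read (both orientations) is anchored by exact `seedLen`-mers tiled
#' along the read and scored at each candidate diagonal by ungapped
#' mismatch counting over the full read; placements exceeding
#' `floor(maxMismatchRate * read_length)` mismatches or extending past a
#' contig end are rejected. The best (fewest-mismatch) placement is
#' reported; exact ties are broken by the lowest contig id, then the lowest
#' position, then the `+` strand, and the alignment is flagged ambiguous
#' (`mapq` 3 instead of 60). Unseeded or over-budget reads are unmapped.
#'
#' @param reads Read table (data.frame `id`, `bases`, `quals`).
#' @param contigs Named character vector or `DNAStringSet`.
#' @param seedLen Exact seed length. Default 21.
#' @param maxMismatchRate Mismatch budget as a fraction of read length.
#'   Default 0.04.
#' @return Alignment table: `readId`, `contigId`, `pos` (0-based),
#'   `strand`, `cigar` (`<len>M`), `mapq` (60 unique / 3 ambiguous), `nm`,
#'   `seq` (read bases in contig orientation), one row per mapped read.
#' @export
mapReads <- function(reads, contigs, seedLen = 21L, maxMismatchRate = 0.04) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  ord <- cOrder(names(seqs))
  seqs <- seqs[ord]  # index in id order so tie-breaks are by contig id
  idx <- buildSeedIndex(seqs, seedLen)
  k <- seedLen
  rows <- vector("list", nrow(reads))
  for (ri in seq_len(nrow(reads))) {
    rd <- reads$bases[ri]
    L <- nchar(rd)
    if (L < k) next
    budget <- floor(maxMismatchRate * L)
    qpos <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    best <- NULL
    tie <- FALSE
    for (strand in c("+", "-")) {
      ord_rd <- if (strand == "+") rd else revComp(rd)
      cand <- NULL
      for (q in qpos) {
        hits <- idx[[substr(ord_rd, q, q + k - 1L)]]
        if (is.null(hits)) next
        cand <- rbind(cand, cbind(hits[, 1L], hits[, 2L] - (q - 1L)))
      }
      if (is.null(cand)) next
      cand <- unique(cand)
      for (t in seq_len(nrow(cand))) {
        ci <- cand[t, 1L]; p0 <- cand[t, 2L]
        if (p0 < 0L || p0 + L > nchar(seqs[[ci]])) next
        mm <- countMismatches(ord_rd, substr(seqs[[ci]], p0 + 1L, p0 + L))
        if (mm > budget) next
        candRec <- list(ci = ci, pos = p0, strand = strand, nm = mm,
                        seq = ord_rd)
        if (is.null(best) || mm < best$nm) {
          best <- candRec; tie <- FALSE
        } else if (mm == best$nm &&
                   !(ci == best$ci && p0 == best$pos &&
                     strand == best$strand)) {
          # deterministic preference: contig id, then pos, then '+' strand
          better <- ci < best$ci ||
            (ci == best$ci && (p0 < best$pos ||
              (p0 == best$pos && strand == "+" && best$strand == "-")))
          if (better) best <- candRec
          tie <- TRUE
        }
      }
    }
    if (is.null(best)) next
    rows[[ri]] <- data.frame(
      readId = reads$id[ri], contigId = names(seqs)[best$ci],
      pos = best$pos, strand = best$strand,
      cigar = paste0(L, "M"), mapq = if (tie) 3L else 60L,
      nm = best$nm, seq = best$seq, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(readId = character(0), contigId = character(0),
                      pos = integer(0), strand = character(0),
                      cigar = character(0), mapq = integer(0),
                      nm = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build per-contig pileups from alignments
#'
#' Tallies per-column base counts, per-column deletion depth, and anchored
#' insertion/deletion events from `M/I/D/S` CIGAR alignments. Alignments
#' with mapping quality below `minMapq` are excluded; per-column depth is
#' capped at `maxDepth` (excess reads are ignored in input order). Indel
#' events are recorded at the column of the base preceding them (the VCF
#' anchor).
#'
#' @param alignments Alignment table ([mapReads()] or [readSam()]).
#' @param contigs Named character vector or `DNAStringSet`.
#' @param minMapq Minimum mapping quality. Default 30.
#' @param maxDepth Per-column depth cap. Default 10000.
#' @return A list of per-contig pileups (class `"contigPileup"` elements):
#'   each has `contigId`, `ref` (character vector of reference bases),
#'   `mat` (5 x L base-count matrix, rows A/C/G/T/N), `del` (per-column
#'   deletion depth) and `events` (environment keyed `"<anchor>|I|<seq>"` /
#'   `"<anchor>|D|<seq>"` with event counts).
#' @export
buildPileup <- function(alignments, contigs, minMapq = 30L,
                        maxDepth = 10000L) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  piles <- lapply(names(seqs), function(id) {
    L <- nchar(seqs[[id]])
    structure(list(
      contigId = id,
      ref = strsplit(seqs[[id]], "", fixed = TRUE)[[1L]],
      mat = matrix(0L, 5L, L, dimnames = list(c("A", "C", "G", "T", "N"),
                                              NULL)),
      del = integer(L),
      events = new.env(parent = emptyenv(), hash = TRUE)
    ), class = "contigPileup")
  })
  names(piles) <- names(seqs)
  aln <- alignments[alignments$mapq >= minMapq &
                    alignments$contigId %in% names(seqs), , drop = FALSE]
  for (r in seq_len(nrow(aln))) {
    p <- piles[[aln$contigId[r]]]
    cig <- parseCigar(aln$cigar[r])
    if (is.null(cig)) next
    refPos <- aln$pos[r]           # 0-based
    qPos <- 0L
    qch <- strsplit(aln$seq[r], "", fixed = TRUE)[[1L]]
    depthAt <- function(cols) p$mat["A", cols] + p$mat["C", cols] +
      p$mat["G", cols] + p$mat["T", cols] + p$mat["N", cols] + p$del[cols]
    for (ops in seq_len(nrow(cig))) {
      op <- cig$op[ops]; len <- cig$len[ops]
      if (op == "S") {
        qPos <- qPos + len
      } else if (op == "M") {
        cols <- (refPos + 1L):(refPos + len)
        bases <- qch[(qPos + 1L):(qPos + len)]
        ok <- depthAt(cols) < maxDepth & bases %in% rownames(p$mat)
        if (any(ok)) {
          ix <- cbind(match(bases[ok], rownames(p$mat)), cols[ok])
          p$mat[ix] <- p$mat[ix] + 1L
        }
        refPos <- refPos + len; qPos <- qPos + len
      } else if (op == "I") {
        ins <- paste(qch[(qPos + 1L):(qPos + len)], collapse = "")
        anchor <- refPos - 1L
        if (anchor >= 0L) {
          key <- paste0(anchor, "|I|", ins)
          p$events[[key]] <- (p$events[[key]] %||% 0L) + 1L
        }
        qPos <- qPos + len
      } else if (op == "D") {
        cols <- (refPos + 1L):(refPos + len)
        ok <- depthAt(cols) < maxDepth
        p$del[cols[ok]] <- p$del[cols[ok]] + 1L
        anchor <- refPos - 1L
        if (anchor >= 0L) {
          delSeq <- paste(p$ref[cols], collapse = "")
          key <- paste0(anchor, "|D|", delSeq)
          p$events[[key]] <- (p$events[[key]] %||% 0L) + 1L
        }
        refPos <- refPos + len
      }
    }
    piles[[aln$contigId[r]]] <- p
  }
  piles
}

#' Inspect one pileup column
#'
#' @param pileup Result of [buildPileup()].
#' @param contigId Contig id.
#' @param pos 0-based column position.
#' @return List with `ref`, `baseCounts` (named A/C/G/T/N), `del`, `depth`,
#'   and `events` (named counts of anchored insertion/deletion events at
#'   this column).
#' @export
pileupColumn <- function(pileup, contigId, pos) {
  p <- pileup[[contigId]]
  stopifnot(!is.null(p), pos >= 0L, pos < length(p$ref))
  bc <- p$mat[, pos + 1L]
  keys <- ls(p$events)
  keys <- keys[startsWith(keys, paste0(pos, "|"))]
  ev <- stats::setNames(vapply(keys, function(k) p$events[[k]], integer(1)),
                        keys)
  list(ref = p$ref[pos + 1L], baseCounts = bc, del = p$del[pos + 1L],
       depth = sum(bc) + p$del[pos + 1L], events = ev)
}
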