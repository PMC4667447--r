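# Pileup-driven correction of spurious insertions/deletions in contig
# sequences. Substitutions are deliberately not corrected: only the
# insertion/deletion errors introduced by the assembler are targeted.

#' Correct spurious insertions and deletions in a contig
#'
#' At columns with depth `>= minDepth`: when the fraction of covering reads
#' that support deletion of the contig base exceeds `majority`, the base is
#' removed (a spurious inserted base in the assembly); when a single
#' inserted string is supported by more than `majority` of the reads
#' spanning the junction, it is inserted after its anchor column (a
#' spurious deletion in the assembly). Conflicting majority edits at one
#' column cancel each other and are logged. Edits are applied right to
#' left so positions remain valid.
#'
#' @param contig A single contig sequence.
#' @param contigPileup The contig's entry from [buildPileup()].
#' @param minDepth Minimum column depth to consider an edit. Default 4.
#' @param majority Support fraction an edit must exceed. Default 0.5.
#' @return List with `seq` (corrected sequence) and `edits` (data.frame
#'   `pos`, `type` (`"del_base"`, `"ins_seq"`, `"conflict"`), `detail`,
#'   `support`, `depth`).
#' @export
correctContig <- function(contig, contigPileup, minDepth = 4L,
                          majority = 0.5) {
  p <- contigPileup
  L <- nchar(contig)
  stopifnot(length(p$ref) == L)
  depth <- colSums(p$mat) + p$del
  # candidate edits per column
  cand <- list()
  addCand <- function(pos, type, detail, support, colDepth) {
    key <- as.character(pos)
    cand[[key]] <<- c(cand[[key]], list(list(
      pos = pos, type = type, detail = detail, support = support,
      depth = colDepth)))
  }
  delCols <- which(depth >= minDepth & p$del / pmax(depth, 1L) > majority)
  for (cix in delCols)
    addCand(cix - 1L, "del_base", p$ref[cix], p$del[cix], depth[cix])
  keys <- ls(p$events)
  insKeys <- keys[grepl("\\|I\\|", keys)]
  for (k in insKeys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    anchor <- as.integer(parts[1L]); ins <- parts[3L]
    colDepth <- depth[anchor + 1L]
    n <- p$events[[k]]
    if (colDepth >= minDepth && n / colDepth > majority)
      addCand(anchor, "ins_seq", ins, n, colDepth)
  }
  logRows <- list()
  edits <- list()
  for (key in names(cand)) {
    cs <- cand[[key]]
    if (length(cs) > 1L) {
      logRows[[length(logRows) + 1L]] <- data.frame(
        pos = cs[[1L]]$pos, type = "conflict",
        detail = paste(vapply(cs, function(c) c$type, character(1)),
                       collapse = "+"),
        support = NA_integer_, depth = cs[[1L]]$depth,
        stringsAsFactors = FALSE)
    } else {
      edits[[length(edits) + 1L]] <- cs[[1L]]
      logRows[[length(logRows) + 1L]] <- data.frame(
        pos = cs[[1L]]$pos, type = cs[[1L]]$type, detail = cs[[1L]]$detail,
        support = cs[[1L]]$support, depth = cs[[1L]]$depth,
        stringsAsFactors = FALSE)
    }
  }
  # apply right-to-left
  seqOut <- contig
  if (length(edits)) {
    ord <- order(-vapply(edits, `[[`, integer(1), "pos"))
    for (e in edits[ord]) {
      if (e$type == "del_base") {
        seqOut <- paste0(substr(seqOut, 1L, e$pos),
                         substr(seqOut, e$pos + 2L, nchar(seqOut)))
      } else {
        seqOut <- paste0(substr(seqOut, 1L, e$pos + 1L), e$detail,
                         substr(seqOut, e$pos + 2L, nchar(seqOut)))
      }
    }
  }
  editLog <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(pos = integer(0), type = character(0), detail = character(0),
               support = integer(0), depth = integer(0),
               stringsAsFactors = FALSE)
  editLog <- editLog[order(editLog$pos), , drop = FALSE]
  rownames(editLog) <- NULL
  list(seq = seqOut, edits = editLog)
}

#' Correct every contig in a set
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param pileup Result of [buildPileup()] on these contigs.
#' @inheritParams correctContig
#' @return List with `contigs` (corrected, same names) and `edits` (one
#'   edit-log data.frame with a `contigId` column).
#' @export
correctContigs <- function(contigs, pileup, minDepth = 4L, majority = 0.5) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  logs <- list()
  for (id in names(seqs)) {
    res <- correctContig(seqs[[id]], pileup[[id]], minDepth, majority)
    seqs[[id]] <- res$seq
    if (nrow(res$edits))
      logs[[length(logs) + 1L]] <- cbind(contigId = id, res$edits)
  }
  list(contigs = seqs,
       edits = if (length(logs)) do.call(rbind, logs) else
         data.frame(contigId = character(0), pos = integer(0),
                    type = character(0), detail = character(0),
                    support = integer(0), depth = integer(0)))
}
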