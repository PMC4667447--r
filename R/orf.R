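# Six-frame ORF discovery and per-contig gene models (5'UTR / CDS / 3'UTR).
# The longest ORF defines the contig's CDS; downstream it drives cluster
# representative selection and variant effect classification.

#' Translate one reading frame
#'
#' Standard genetic code; translation runs to the end of the sequence, the
#' incomplete trailing codon is dropped, stop codons render `*`, and any
#' codon containing a non-ACGT base renders `X`.
#'
#' @param nt A single nucleotide string.
#' @param frame Frame offset, 0, 1 or 2.
#' @return Protein string (possibly empty).
#' @export
#' @examples
#' translateFrame("ATGAAATAG", 0)  # "MK*"
translateFrame <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  L <- nchar(nt)
  nc <- (L - frame) %/% 3L
  if (nc <= 0L) return("")
  starts <- frame + 1L + 3L * (seq_len(nc) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ORFs of a single strand string: returns data.frame with 0-based nt
# coordinates on that strand, codon-resolved.
orfScanStrand <- function(s, minLenNt, mode) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    prot <- translateFrame(s, f)
    nc <- nchar(prot)
    if (nc == 0L) next
    aa <- strsplit(prot, "", fixed = TRUE)[[1L]]
    stops <- which(aa == "*")
    # regions of codons strictly between stops (1-based codon indices)
    regStart <- c(1L, stops + 1L)
    regEnd <- c(stops - 1L, nc)
    hasStop <- c(rep(TRUE, length(stops)), FALSE)
    for (r in seq_along(regEnd)) {
      rs <- regStart[r]; re <- regEnd[r]
      if (rs > re) next
      first <- if (mode == "atg") {
        m <- which(aa[rs:re] == "M")
        if (!length(m)) next
        rs + m[1L] - 1L
      } else rs
      complete3p <- hasStop[r]
      lastCodon <- if (complete3p) re + 1L else re  # include stop codon
      startNt <- f + 3L * (first - 1L)
      endNt <- f + 3L * lastCodon
      protein <- paste(aa[first:re], collapse = "")
      span <- endNt - startNt
      if (span < minLenNt) next
      out[[length(out) + 1L]] <- data.frame(
        start = startNt, end = endNt, complete3p = complete3p,
        protein = protein, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      complete3p = logical(0), protein = character(0)))
  do.call(rbind, out)
}

#' Find the longest open reading frame over six frames
#'
#' In the default `"atg"` mode an ORF runs from an `ATG` to the next
#' in-frame stop codon (included in the nucleotide span) or, when no stop
#' follows, to the last complete codon before the contig end (flagged
#' incomplete at the 3' end). In `"between-stops"` mode the ORF starts at
#' the first codon after the previous stop (or the frame start), which need
#' not be a methionine. The longest ORF by nucleotide span is returned;
#' ties prefer the `+` strand, then the smallest forward-strand start.
#'
#' @param seq A single nucleotide string.
#' @param minLenNt Minimum ORF span in nucleotides (multiple of 3,
#'   `>= 3`). Default 90 (30 codons).
#' @param mode `"atg"` (default) or `"between-stops"`.
#' @return `NULL` when no qualifying ORF exists, else a list with `start`,
#'   `end` (0-based half-open, forward strand of the input), `strand`,
#'   `complete5p`, `complete3p` and `protein` (no terminal stop symbol).
#' @export
#' @examples
#' findLongestOrf("CCATGAAATAGCC", minLenNt = 3)
findLongestOrf <- function(seq, minLenNt = 90L, mode = c("atg", "between-stops")) {
  mode <- match.arg(mode)
  stopifnot(minLenNt >= 3L, minLenNt %% 3L == 0L)
  L <- nchar(seq)
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revComp(seq)
    sc <- orfScanStrand(s, minLenNt, mode)
    if (!nrow(sc)) next
    if (strand == "+") {
      sc$fstart <- sc$start; sc$fend <- sc$end
    } else {
      sc$fstart <- L - sc$end; sc$fend <- L - sc$start
    }
    sc$strand <- strand
    cands[[strand]] <- sc
  }
  if (!length(cands)) return(NULL)
  all <- do.call(rbind, cands)
  span <- all$end - all$start
  # longest span; tie: '+' before '-'; then smallest forward start
  ord <- order(-span, all$strand != "+", all$fstart)
  b <- all[ord[1L], ]
  list(start = b$fstart, end = b$fend, strand = b$strand,
       complete5p = mode == "atg", complete3p = b$complete3p,
       protein = b$protein)
}

#' Longest-ORF table for a contig set
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @inheritParams findLongestOrf
#' @return data.frame with one row per contig: `contigId`, `orfLen`
#'   (nucleotide span, 0 when no ORF), `start`, `end`, `strand`,
#'   `complete3p`, `protein` (`NA`/empty when no ORF).
#' @export
longestOrfTable <- function(contigs, minLenNt = 90L,
                            mode = c("atg", "between-stops")) {
  mode <- match.arg(mode)
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  rows <- lapply(names(seqs), function(id) {
    o <- findLongestOrf(seqs[[id]], minLenNt, mode)
    if (is.null(o))
      data.frame(contigId = id, orfLen = 0L, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_,
                 complete3p = NA, protein = NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(contigId = id, orfLen = o$end - o$start, start = o$start,
                 end = o$end, strand = o$strand, complete3p = o$complete3p,
                 protein = o$protein, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene model (5'UTR / CDS / 3'UTR) from a contig's longest ORF
#'
#' Intervals are expressed in transcript orientation (the contig is
#' reverse-complemented first when the ORF lies on the `-` strand), 0-based
#' half-open, and tile the contig: `utr5` ends where `cds` starts, `cds`
#' ends where `utr3` starts.
#'
#' @param contigId Contig id.
#' @param contigLen Contig length in nucleotides.
#' @param orf Result of [findLongestOrf()] (non-`NULL`).
#' @return One-row data.frame: `contigId`, `strand`, `utr5Start`,
#'   `utr5End`, `cdsStart`, `cdsEnd`, `utr3Start`, `utr3End`.
#' @export
geneModelFromOrf <- function(contigId, contigLen, orf) {
  stopifnot(!is.null(orf))
  if (orf$strand == "+") {
    cs <- orf$start; ce <- orf$end
  } else {
    cs <- contigLen - orf$end; ce <- contigLen - orf$start
  }
  data.frame(contigId = contigId, strand = orf$strand,
             utr5Start = 0L, utr5End = cs,
             cdsStart = cs, cdsEnd = ce,
             utr3Start = ce, utr3End = contigLen,
             stringsAsFactors = FALSE)
}

#' Gene models for a contig set
#'
#' @inheritParams longestOrfTable
#' @return data.frame of gene models (see [geneModelFromOrf()]) for the
#'   contigs that have a qualifying ORF.
#' @export
geneModels <- function(contigs, minLenNt = 90L,
                       mode = c("atg", "between-stops")) {
  mode <- match.arg(mode)
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  rows <- lapply(names(seqs), function(id) {
    o <- findLongestOrf(seqs[[id]], minLenNt, mode)
    if (is.null(o)) return(NULL)
    geneModelFromOrf(id, nchar(seqs[[id]]), o)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(contigId = character(0), strand = character(0),
                      utr5Start = integer(0), utr5End = integer(0),
                      cdsStart = integer(0), cdsEnd = integer(0),
                      utr3Start = integer(0), utr3End = integer(0)))
  do.call(rbind, rows)
}
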