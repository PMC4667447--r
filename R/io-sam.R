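# Minimal SAM text I/O. SAM is the interoperability surface: externally
# produced alignments can be imported, and the built-in mapper's alignments
# can be exported. Only QNAME, FLAG, RNAME, POS, MAPQ, CIGAR and SEQ are
# used; everything else is ignored on input and written as '*'/0 on output.

samCigarOps <- c("M", "I", "D", "S")

# Parse a CIGAR string into a data.frame(op, len); NULL when malformed or
# containing an unsupported op.
parseCigar <- function(cigar) {
  if (cigar == "*") return(NULL)
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
    return(NULL)
  op <- substr(toks, nchar(toks), nchar(toks))
  if (!all(op %in% samCigarOps)) return(NULL)
  data.frame(op = op, len = as.integer(sub(".$", "", toks)),
             stringsAsFactors = FALSE)
}

#' Import alignments from a SAM text file
#'
#' Parses the minimal subset of SAM used by the pipeline. Unmapped records
#' (flag bit 0x4 or RNAME `*`) are dropped; records whose CIGAR is malformed
#' or uses an operation outside `M/I/D/S` are skipped with one summary
#' warning.
#'
#' @param path Path to an uncompressed SAM file.
#' @return Alignment table: data.frame with columns `readId`, `contigId`,
#'   `pos` (0-based leftmost reference position), `strand` (`+`/`-` from
#'   flag bit 0x10), `cigar`, `mapq`, `nm` (`NA` when absent) and `seq`
#'   (read bases in reference orientation).
#' @export
readSam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.frame(readId = character(0), contigId = character(0),
                      pos = integer(0), strand = character(0),
                      cigar = character(0), mapq = integer(0),
                      nm = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 11L
  if (any(short)) {
    warning(sprintf("%d SAM record(s) with fewer than 11 fields skipped",
                    sum(short)))
    fields <- fields[!short]
    if (!length(fields)) return(empty)
  }
  flag <- vapply(fields, function(f) as.integer(f[2L]), integer(1))
  rname <- vapply(fields, `[`, character(1), 3L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  fields <- fields[mapped]; flag <- flag[mapped]
  if (!length(fields)) return(empty)
  cigar <- vapply(fields, `[`, character(1), 6L)
  ok <- !vapply(cigar, function(cg) is.null(parseCigar(cg)), logical(1))
  if (any(!ok))
    warning(sprintf("%d SAM record(s) with malformed CIGAR skipped", sum(!ok)))
  fields <- fields[ok]; flag <- flag[ok]; cigar <- cigar[ok]
  if (!length(fields)) return(empty)
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1))
  data.frame(
    readId = vapply(fields, `[`, character(1), 1L),
    contigId = vapply(fields, `[`, character(1), 3L),
    pos = to0based(vapply(fields, function(f) as.integer(f[4L]), integer(1))),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    cigar = cigar,
    mapq = vapply(fields, function(f) as.integer(f[5L]), integer(1)),
    nm = nm,
    seq = vapply(fields, `[`, character(1), 10L),
    stringsAsFactors = FALSE
  )
}

#' Export alignments as SAM text
#'
#' @param alignments Alignment table (see [readSam()] for columns).
#' @param contigs Named character vector or `DNAStringSet` of the reference
#'   contigs (used for the `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, contigs, path) {
  if (methods::is(contigs, "DNAStringSet")) {
    lens <- Biostrings::width(contigs)
    nms <- names(contigs)
  } else {
    lens <- nchar(contigs)
    nms <- names(contigs)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", nms, lens))
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                    alignments$readId, flag, alignments$contigId,
                    to1based(alignments$pos), alignments$mapq,
                    alignments$cigar, alignments$seq,
                    ifelse(is.na(alignments$nm), 0L, alignments$nm))
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
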