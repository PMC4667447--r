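# FASTQ reading/writing. Reads are carried through the pipeline as a plain
# data.frame ("read table") with columns id / bases / quals so that the
# N-based cleansing operations can work on bases and qualities in sync
# without case folding; conversion to Biostrings containers is one call away
# for users who want it.

#' Read a 4-line-record FASTQ file
#'
#' Strict parser for the plain (uncompressed) 4-line FASTQ dialect used
#' throughout the pipeline: `@id`, bases, `+`, Phred+33 qualities. Bases are
#' not case folded.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with character columns `id`, `bases`, `quals`, one
#'   row per read, in file order. Zero rows for an empty file.
#' @details A truncated record or a base/quality length mismatch is an error
#'   naming the offending line number.
#' @seealso [writeFastq()], [cleanseReads()]
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeFastq(data.frame(id = "r1", bases = "ACGT", quals = "IIII"), fq)
#' readFastq(fq)
readFastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  n <- length(lines)
  # trailing blank lines are tolerated
  while (n > 0L && !nzchar(lines[n])) n <- n - 1L
  if (n == 0L)
    return(data.frame(id = character(0), bases = character(0),
                      quals = character(0), stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at line %d in '%s'", n + 1L, path))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ header at line %d in '%s'",
                 idx[bad[1L]], path))
  plus <- lines[idx + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ separator at line %d in '%s'",
                 idx[bad[1L]] + 2L, path))
  bases <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad))
    stop(sprintf(
      "base/quality length mismatch at line %d in '%s'",
      idx[bad[1L]] + 3L, path))
  ids <- sub("^@", "", hdr)
  if (any(!nzchar(ids))) stop("empty read id in FASTQ")
  data.frame(id = ids, bases = bases, quals = quals, stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' Inverse of [readFastq()]: `readFastq(writeFastq(x, f))` reproduces `x`.
#'
#' @param reads Read table (data.frame with `id`, `bases`, `quals`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("id", "bases", "quals") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$bases) != nchar(reads$quals)))
    stop("base/quality length mismatch in read table")
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$id), reads$bases, "+", reads$quals)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Convert a read table to a QualityScaledDNAStringSet
#'
#' @param reads Read table as returned by [readFastq()].
#' @return A [Biostrings::QualityScaledDNAStringSet] (Phred+33 qualities).
#' @export
asQualityScaledReads <- function(reads) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$bases, reads$id)),
    Biostrings::PhredQuality(reads$quals))
}
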