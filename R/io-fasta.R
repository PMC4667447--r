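# FASTA I/O (via Biostrings) and assembler-header parsing.

#' Read / write contig FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] fixing the dialect used by the pipeline
#' (unwrapped sequence lines on output; full header line kept as the name).
#'
#' @param path File path.
#' @param x A named character vector or [Biostrings::DNAStringSet].
#' @return `readFasta()` returns a [Biostrings::DNAStringSet];
#'   `writeFasta()` returns `path` invisibly.
#' @export
readFasta <- function(path) {
  stopifnot(file.exists(path))
  Biostrings::readDNAStringSet(path)
}

#' @rdname readFasta
#' @export
writeFasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Parse an Oases-style contig header
#'
#' Extracts locus, transcript index and reported length from headers of the
#' form `Locus_<L>_Transcript_<T>/<N>_Confidence_<c>_Length_<len>`. Parsing
#' is lenient by design: a header that does not match yields all-`NA`
#' metadata with a warning, so heterogeneous contig sets pass through.
#'
#' @param headers Character vector of header lines (without the `>`).
#' @param pattern Regular expression with four capture groups (locus,
#'   transcript index, confidence, length); the default matches the Oases
#'   convention.
#' @return data.frame with columns `id` (the full header), `locus`
#'   (character), `transcriptIndex` (integer), `confidence` (numeric),
#'   `length` (integer); `NA`s where absent.
#' @export
#' @examples
#' parseOasesHeader("Locus_7_Transcript_2/3_Confidence_0.600_Length_1320")
parseOasesHeader <- function(headers,
    pattern = "Locus_([^_]+)_Transcript_([0-9]+)/[0-9]+_Confidence_([0-9.]+)_Length_([0-9]+)") {
  m <- regmatches(headers, regexec(pattern, headers))
  ok <- lengths(m) == 5L
  if (any(!ok))
    warning(sprintf("%d header(s) did not match the locus pattern; metadata set to NA",
                    sum(!ok)))
  get_g <- function(i, as) {
    v <- rep(NA_character_, length(headers))
    v[ok] <- vapply(m[ok], `[`, character(1), i)
    as(v)
  }
  data.frame(
    id = headers,
    locus = get_g(2L, as.character),
    transcriptIndex = get_g(3L, function(v) as.integer(v)),
    confidence = get_g(4L, function(v) as.numeric(v)),
    length = get_g(5L, function(v) as.integer(v)),
    stringsAsFactors = FALSE
  )
}
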