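# Reads-per-million filtering and the per-library count matrix.

#' Reads-per-million keep decision
#'
#' A contig is kept when its mapped-read count scaled to reads per million
#' of the library total reaches `threshold`: `count / total * 1e6 >=
#' threshold`, so exactly 2 RPM is kept at the default threshold (only
#' strictly fewer than two reads per million are excluded).
#'
#' @param count Mapped-read count(s), vectorized.
#' @param libraryTotal Library read total (the RPM denominator; by pipeline
#'   default the cleaned-read total). Must be `> 0`.
#' @param threshold RPM threshold. Default 2.
#' @return Logical vector of keep flags.
#' @export
rpmFilter <- function(count, libraryTotal, threshold = 2.0) {
  if (any(libraryTotal <= 0)) stop("libraryTotal must be > 0")
  count / libraryTotal * 1e6 >= threshold
}

#' Build the contigs-by-libraries count matrix
#'
#' `counts[i, j]` is the number of mapped reads of library `j` whose best
#' placement is contig `i`; each mapped read contributes to exactly one
#' cell and unmapped reads are excluded.
#'
#' @param perLibraryAlignments Named list (library id -> alignment table)
#'   of alignments against the same final contig set.
#' @param contigIds Character vector of the final contig universe (row
#'   order of the result).
#' @param libraryTotals Named per-library read totals (RPM denominators;
#'   typically cleaned-read totals). Names must cover the libraries.
#' @return A \linkS4class{ContigCounts}.
#' @export
buildCountMatrix <- function(perLibraryAlignments, contigIds,
                             libraryTotals) {
  libs <- names(perLibraryAlignments)
  stopifnot(!is.null(libs), all(libs %in% names(libraryTotals)))
  cts <- matrix(0L, nrow = length(contigIds), ncol = length(libs),
                dimnames = list(contigIds, libs))
  for (lib in libs) {
    aln <- perLibraryAlignments[[lib]]
    if (!all(aln$contigId %in% contigIds))
      stop("alignments reference contigs outside the given contig universe")
    if (anyDuplicated(aln$readId))
      stop("more than one alignment per read in library ", lib)
    if (nrow(aln)) {
      tab <- table(aln$contigId)
      cts[names(tab), lib] <- as.integer(tab)
    }
  }
  ContigCounts(cts, libraryTotals[libs])
}
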