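# Count-matrix container construction and TSV round-trip.

#' Construct a ContigCounts object
#'
#' @param counts Integer matrix, contigs in rows (rownames = contig ids),
#'   libraries in columns (colnames = library ids).
#' @param totals Named numeric vector of per-library read totals (the RPM
#'   denominator); names must match `colnames(counts)`.
#' @return A \linkS4class{ContigCounts}.
#' @export
ContigCounts <- function(counts, totals) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(names(totals))) names(totals) <- colnames(counts)
  totals <- totals[colnames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(total = as.numeric(totals),
                                   row.names = colnames(counts)))
  methods::new("ContigCounts", se)
}

#' Write / read the count matrix as TSV
#'
#' The layout is a `contig<TAB>lib1<TAB>lib2...` header row over integer
#' counts, preceded by one comment line `#library_totals` carrying the RPM
#' denominators so the file round-trips losslessly.
#'
#' @param x A \linkS4class{ContigCounts}.
#' @param path File path.
#' @return `writeCountsTsv()` returns `path` invisibly; `readCountsTsv()`
#'   returns a \linkS4class{ContigCounts}.
#' @export
writeCountsTsv <- function(x, path) {
  stopifnot(methods::is(x, "ContigCounts"))
  con <- file(path, "w")
  on.exit(close(con))
  tot <- libraryTotals(x)
  writeLines(paste(c("#library_totals", format(tot, scientific = FALSE,
                                               trim = TRUE)),
                   collapse = "\t"), con)
  writeLines(paste(c("contig", colnames(x)), collapse = "\t"), con)
  cts <- SummarizedExperiment::assay(x, "counts")
  if (nrow(cts))
    writeLines(paste(rownames(cts),
                     apply(cts, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  totline <- NULL
  if (length(lines) && startsWith(lines[1L], "#library_totals")) {
    totline <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
    lines <- lines[-1L]
  }
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  libs <- hdr[-1L]
  body <- lines[-1L]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(f, `[`, character(1), 1L)
    cts <- t(vapply(f, function(x) as.integer(x[-1L]),
                    integer(length(libs))))
    if (length(libs) == 1L) cts <- matrix(as.integer(cts), ncol = 1L)
    dimnames(cts) <- list(ids, libs)
  } else {
    cts <- matrix(integer(0), nrow = 0L, ncol = length(libs),
                  dimnames = list(character(0), libs))
  }
  totals <- if (!is.null(totline)) stats::setNames(as.numeric(totline), libs)
            else colSums(cts)
  ContigCounts(cts, totals)
}
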