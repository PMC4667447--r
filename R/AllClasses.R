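#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Contig count matrix with per-library totals
#'
#' A contigs-by-libraries read-count container built on
#' \linkS4class{SummarizedExperiment}. The single assay `"counts"` holds
#' integer mapped-read counts; `colData()$total` carries the per-library
#' read totals used as the reads-per-million (RPM) denominator — by default
#' the library's cleaned-read total, which may exceed its mapped total.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [buildCountMatrix()], [rpmFilter()], [poolLibraries()]
#' @export
setClass("ContigCounts", contains = "SummarizedExperiment")

setValidity("ContigCounts", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (!"total" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'total' (per-library read total) is required")
  if (length(msg) == 0L) {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    tot <- SummarizedExperiment::colData(object)$total
    if (any(colSums(cts) > tot))
      msg <- c(msg, "column sums of counts must not exceed library totals")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "unique contig ids (rownames) are required")
  }
  if (length(msg)) msg else TRUE
})

#' Greedy identity clustering result
#'
#' Partition of a sequence set produced by [greedyCluster()]: each input id
#' belongs to exactly one cluster; the cluster representative is the (longest)
#' founder sequence.
#'
#' @slot representatives character vector, one representative id per cluster.
#' @slot members list of character vectors, parallel to `representatives`;
#'   each vector contains the member ids of that cluster (the representative
#'   included).
#' @slot level `"nt"` or `"aa"` — whether identity was computed on nucleotide
#'   sequences (best of both orientations) or protein sequences (forward only).
#' @slot threshold identity threshold in (0, 1] used for membership.
#' @seealso [greedyCluster()], [selectByLongestOrf()]
#' @export
setClass("ContigClusters",
  representation(
    representatives = "character",
    members = "list",
    level = "character",
    threshold = "numeric"
  )
)

setValidity("ContigClusters", function(object) {
  msg <- character(0)
  if (length(object@representatives) != length(object@members))
    msg <- c(msg, "representatives and members must be parallel")
  if (!object@level %in% c("nt", "aa"))
    msg <- c(msg, "level must be 'nt' or 'aa'")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in (0, 1]")
  all_ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_ids))
    msg <- c(msg, "members must be disjoint across clusters")
  if (length(object@members) &&
      !all(mapply(function(r, m) r %in% m,
                  object@representatives, object@members)))
    msg <- c(msg, "each representative must be among its cluster's members")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContigClusters-class number of clusters.
#' @param x,object A `ContigClusters` object.
#' @export
setMethod("length", "ContigClusters", function(x) length(x@representatives))

setMethod("show", "ContigClusters", function(object) {
  n <- sum(lengths(object@members))
  cat(sprintf(
    "ContigClusters: %d cluster(s) over %d sequence(s) [%s identity >= %.2f]\n",
    length(object), n, object@level, object@threshold))
})

setMethod("show", "ContigCounts", function(object) {
  cat(sprintf("ContigCounts: %d contig(s) x %d library(ies)\n",
              nrow(object), ncol(object)))
  cat("library totals:",
      paste(sprintf("%s=%d", colnames(object),
                    SummarizedExperiment::colData(object)$total),
            collapse = ", "), "\n")
})
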