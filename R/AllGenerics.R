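#' Accessors for ContigClusters and ContigCounts
#'
#' @param x A \linkS4class{ContigClusters} or \linkS4class{ContigCounts}
#'   object.
#' @return `representatives()` and `clusterMembers()` return the
#'   representative ids and the member-id list of a `ContigClusters`;
#'   `identityLevel()` and `identityThreshold()` its parameters.
#'   `libraryTotals()` returns the named per-library read totals of a
#'   `ContigCounts`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("identityLevel", function(x) standardGeneric("identityLevel"))

#' @rdname accessors
#' @export
setGeneric("identityThreshold", function(x) standardGeneric("identityThreshold"))

#' @rdname accessors
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname accessors
#' @export
setMethod("representatives", "ContigClusters", function(x) x@representatives)

#' @rdname accessors
#' @export
setMethod("clusterMembers", "ContigClusters", function(x) {
  stats::setNames(x@members, x@representatives)
})

#' @rdname accessors
#' @export
setMethod("identityLevel", "ContigClusters", function(x) x@level)

#' @rdname accessors
#' @export
setMethod("identityThreshold", "ContigClusters", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("libraryTotals", "ContigCounts", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$total, colnames(x))
})
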