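# Redundancy removal: cd-hit-style pairwise identity, greedy incremental
# clustering, and longest-ORF representative selection.

aaIdentityMatrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- Biostrings::AA_ALPHABET
      m <- matrix(-1, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      mat <<- m
    }
    mat
  }
})

alignIdentity <- function(shorter, longer, level) {
  if (level == "nt") {
    aln <- Biostrings::pairwiseAlignment(
      pattern = shorter, subject = longer, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 2)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(shorter),
      subject = Biostrings::AAString(longer),
      type = "global-local", substitutionMatrix = aaIdentityMatrix(),
      gapOpening = 4, gapExtension = 2)
  }
  Biostrings::nmatch(aln) / nchar(shorter)
}

#' cd-hit-style pairwise sequence identity
#'
#' Identity is the number of identical aligned positions divided by the
#' length of the shorter sequence (the cd-hit convention, so a sequence
#' exactly contained in a longer one scores 1.0). The shorter sequence is
#' aligned globally within the longer one; at nucleotide level the better
#' of the forward and reverse-complement orientations is taken, at protein
#' level only the forward orientation.
#'
#' @param a,b Sequences (single strings).
#' @param level `"nt"` (default) or `"aa"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwiseIdentity <- function(a, b, level = c("nt", "aa")) {
  level <- match.arg(level)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (nchar(a) <= nchar(b)) { shorter <- a; longer <- b }
  else { shorter <- b; longer <- a }
  id <- alignIdentity(shorter, longer, level)
  if (level == "nt") {
    idRc <- alignIdentity(revComp(shorter), longer, level)
    id <- max(id, idRc)
  }
  min(id, 1)
}

seqWords <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  unique(substring(s, starts, starts + w - 1L))
}

#' Greedy incremental identity clustering
#'
#' Sequences are sorted by length descending (ties broken by id ascending)
#' and processed in order: each sequence joins the first existing cluster
#' whose representative it matches at `>= threshold` identity
#' ([pairwiseIdentity()]), otherwise it founds a new cluster. The procedure
#' is deterministic. An optional shared-word prefilter skips alignments
#' against representatives that share no `wordSize`-mer with the query
#' (in either orientation at nucleotide level); it is a performance device
#' only and conservative at the thresholds used here.
#'
#' @param sequences Named character vector or `XStringSet` with unique ids.
#' @param threshold Identity threshold in (0, 1].
#' @param level `"nt"` or `"aa"`.
#' @param wordFilter Enable the shared-word prefilter. Default `TRUE`.
#' @param wordSize Prefilter word length. Default 10 (nt) / 4 (aa).
#' @return A \linkS4class{ContigClusters}.
#' @export
greedyCluster <- function(sequences, threshold, level = c("nt", "aa"),
                          wordFilter = TRUE, wordSize = NULL) {
  level <- match.arg(level)
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- if (methods::is(sequences, "XStringSet"))
    stats::setNames(as.character(sequences), names(sequences)) else sequences
  if (anyDuplicated(names(seqs))) stop("sequence ids must be unique")
  if (is.null(wordSize)) wordSize <- if (level == "nt") 10L else 4L
  ord <- cOrder(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  repIds <- character(0)
  repWords <- list()
  members <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    s <- seqs[[i]]
    qw <- if (wordFilter) {
      w <- seqWords(s, wordSize)
      if (level == "nt") unique(c(w, revComp(w))) else w
    } else NULL
    placed <- FALSE
    for (r in seq_along(repIds)) {
      if (wordFilter && !any(qw %in% repWords[[r]])) next
      if (pairwiseIdentity(s, seqs[[repIds[r]]], level) >= threshold) {
        members[[r]] <- c(members[[r]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIds <- c(repIds, id)
      members[[length(repIds)]] <- id
      repWords[[length(repIds)]] <- if (wordFilter) seqWords(s, wordSize)
                                    else character(0)
    }
  }
  methods::new("ContigClusters", representatives = repIds, members = members,
               level = level, threshold = threshold)
}

#' Select cluster representatives by longest ORF
#'
#' For each cluster, the representative is the member with the longest ORF
#' (nucleotide span); an exact ORF-length tie goes to the longer contig,
#' and any remaining tie to the lexicographically smallest id.
#'
#' @param clusters A \linkS4class{ContigClusters}.
#' @param orfLengths Named numeric vector of longest-ORF nucleotide spans
#'   per member id (0 for members without an ORF); see [longestOrfTable()].
#' @param contigLengths Named numeric vector of contig lengths per member
#'   id.
#' @return Character vector of selected ids, one per cluster, in cluster
#'   order.
#' @export
selectByLongestOrf <- function(clusters, orfLengths, contigLengths) {
  vapply(clusters@members, function(ids) {
    ol <- orfLengths[ids]
    ol[is.na(ol)] <- 0
    cl <- contigLengths[ids]
    ord <- cOrder(-ol, -cl, ids)
    ids[ord[1L]]
  }, character(1))
}
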