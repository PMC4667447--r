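# Overlap merging of contigs: exact-seed anchored detection of dovetail and
# containment overlaps (both orientations) and majority-consensus merging of
# consistent overlap-graph components.

hammingIdentity <- function(x, y) {
  # identical characters at aligned positions of two equal-length strings
  cx <- strsplit(x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(y, "", fixed = TRUE)[[1L]]
  sum(cx == cy) / length(cx)
}

# Best ungapped overlap between a and oriented b at candidate diagonal
# offsets (offset = position of b's first base in a's coordinates, may be
# negative).
bestDiagonalOverlap <- function(a, b, offsets, minOverlap, minIdentity) {
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  for (d in offsets) {
    s <- max(0L, d); e <- min(la, d + lb)
    ov <- e - s
    if (ov < minOverlap) next
    idf <- hammingIdentity(substr(a, s + 1L, e), substr(b, s - d + 1L, e - d))
    if (idf < minIdentity) next
    if (is.null(best) || ov > best$overlapLen ||
        (ov == best$overlapLen && idf > best$identity))
      best <- list(offset = d, overlapLen = ov, identity = idf)
  }
  best
}

#' Find significant overlaps between contigs
#'
#' Detects suffix-prefix (dovetail) and containment overlaps by exact-seed
#' anchoring followed by ungapped comparison along the seeded diagonal, in
#' both orientations. An edge is reported when the overlap reaches
#' `minOverlap` bases at `>= minIdentity` identity; the best (longest, then
#' highest-identity) overlap per contig pair and orientation is kept.
#'
#' @param contigs Named character vector or `DNAStringSet` with unique ids.
#' @param minOverlap Minimum overlap length in bases. Default 60.
#' @param minIdentity Minimum identity over the overlap. Default 0.96.
#' @param seedLen Exact seed length for anchoring. Default 16.
#' @return data.frame of overlap edges: `idA`, `idB`, `orientation`
#'   (`"same"`/`"reverse"`), `offset` (start of oriented B in A
#'   coordinates, 0-based, possibly negative), `overlapLen`, `identity`.
#' @export
findContigOverlaps <- function(contigs, minOverlap = 60L, minIdentity = 0.96,
                               seedLen = 16L) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  if (anyDuplicated(names(seqs))) stop("contig ids must be unique")
  ids <- names(seqs)
  emptyEdges <- data.frame(idA = character(0), idB = character(0),
                           orientation = character(0), offset = integer(0),
                           overlapLen = integer(0), identity = numeric(0),
                           stringsAsFactors = FALSE)
  if (length(seqs) < 2L) return(emptyEdges)
  # seed index: word -> data.frame(contig index, 0-based position)
  k <- seedLen
  seedTab <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[[i]])
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    data.frame(word = substring(seqs[[i]], st, st + k - 1L),
               contig = i, pos = st - 1L, stringsAsFactors = FALSE)
  }))
  index <- split(seedTab[c("contig", "pos")], seedTab$word)
  edges <- list()
  for (i in seq_along(seqs)[-length(seqs)]) {
    a <- seqs[[i]]
    for (j in seq(i + 1L, length(seqs))) {
      for (orient in c("same", "reverse")) {
        b <- if (orient == "same") seqs[[j]] else revComp(seqs[[j]])
        lb <- nchar(b)
        if (lb < k) next
        st <- seq_len(lb - k + 1L)
        words <- substring(b, st, st + k - 1L)
        hit <- index[words]
        offs <- unlist(lapply(seq_along(hit), function(t) {
          h <- hit[[t]]
          if (is.null(h)) return(integer(0))
          h$pos[h$contig == i] - (st[t] - 1L)
        }), use.names = FALSE)
        if (!length(offs)) next
        best <- bestDiagonalOverlap(a, b, unique(offs), minOverlap,
                                    minIdentity)
        if (!is.null(best))
          edges[[length(edges) + 1L]] <- data.frame(
            idA = ids[i], idB = ids[j], orientation = orient,
            offset = best$offset, overlapLen = best$overlapLen,
            identity = best$identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) return(emptyEdges)
  do.call(rbind, edges)
}

#' Merge contigs along consistent overlap-graph components
#'
#' Connected components of the overlap graph are laid out by breadth-first
#' propagation of edge offsets/orientations and merged into a single
#' consensus sequence: the base at each layout column is the majority
#' across contributing contigs, ties going to the base of the longest
#' contributor (then the smallest id). Components whose edges imply
#' conflicting placements are left unmerged and flagged in the report.
#'
#' @param contigs Named character vector or `DNAStringSet`.
#' @param edges Edge table from [findContigOverlaps()].
#' @return List with `contigs` (merged set: consensus per merged component,
#'   named after its longest member, plus untouched singletons/inconsistent
#'   members) and `report` (data.frame `component`, `members`, `merged`).
#' @export
mergeOverlapping <- function(contigs, edges) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  ids <- names(seqs)
  # union-find
  parent <- stats::setNames(ids, ids)
  findRoot <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges))
    for (r in seq_len(nrow(edges))) {
      ra <- findRoot(edges$idA[r]); rb <- findRoot(edges$idB[r])
      if (ra != rb) parent[[rb]] <- ra
    }
  comp <- vapply(ids, findRoot, character(1))
  out <- character(0)
  reportRows <- list()
  flipO <- function(o) if (o == "+") "-" else "+"
  for (cc in unique(comp)) {
    memb <- ids[comp == cc]
    if (length(memb) == 1L) {
      out[memb] <- seqs[[memb]]
      reportRows[[length(reportRows) + 1L]] <- data.frame(
        component = cc, members = memb, merged = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    es <- edges[edges$idA %in% memb | edges$idB %in% memb, , drop = FALSE]
    # BFS layout from the longest member
    root <- memb[cOrder(-nchar(seqs[memb]), memb)][1L]
    orient <- stats::setNames(rep(NA_character_, length(memb)), memb)
    offset <- stats::setNames(rep(NA_integer_, length(memb)), memb)
    orient[root] <- "+"; offset[root] <- 0L
    queue <- root
    consistent <- TRUE
    while (length(queue) && consistent) {
      u <- queue[1L]; queue <- queue[-1L]
      inc <- es[es$idA == u | es$idB == u, , drop = FALSE]
      for (r in seq_len(nrow(inc))) {
        e <- inc[r, ]
        # express edge as: oriented v starts at `off` in u's forward frame
        if (e$idA == u) {
          v <- e$idB
          vRelO <- if (e$orientation == "same") "+" else "-"
          off <- e$offset
        } else {
          v <- e$idA
          vRelO <- if (e$orientation == "same") "+" else "-"
          # invert: A starts at -offset in oriented-B frame
          if (e$orientation == "same") off <- -e$offset
          else off <- e$offset + nchar(seqs[[e$idB]]) - nchar(seqs[[e$idA]])
        }
        lu <- nchar(seqs[[u]]); lv <- nchar(seqs[[v]])
        if (orient[u] == "+") {
          vO <- if (vRelO == "+") "+" else "-"
          vOff <- offset[u] + off
        } else {
          vO <- if (vRelO == "+") "-" else "+"
          vOff <- offset[u] + lu - off - lv
        }
        if (is.na(orient[v])) {
          orient[v] <- vO; offset[v] <- vOff
          queue <- c(queue, v)
        } else if (orient[v] != vO || offset[v] != vOff) {
          consistent <- FALSE
          break
        }
      }
    }
    if (!consistent || any(is.na(orient))) {
      out[memb] <- unlist(seqs[memb])
      reportRows[[length(reportRows) + 1L]] <- data.frame(
        component = cc, members = paste(memb, collapse = ","),
        merged = FALSE, stringsAsFactors = FALSE)
      next
    }
    shift <- min(offset)
    offset <- offset - shift
    span <- max(offset[memb] +
                vapply(memb, function(m) nchar(seqs[[m]]), integer(1)))
    # majority consensus; ties -> base of the longest contributor
    membOrd <- memb[cOrder(-vapply(memb, function(m) nchar(seqs[[m]]),
                                  integer(1)), memb)]
    colBase <- matrix(NA_character_, nrow = length(membOrd), ncol = span)
    for (mi in seq_along(membOrd)) {
      m <- membOrd[mi]
      s <- if (orient[m] == "+") seqs[[m]] else revComp(seqs[[m]])
      chs <- strsplit(s, "", fixed = TRUE)[[1L]]
      colBase[mi, (offset[m] + 1L):(offset[m] + length(chs))] <- chs
    }
    cons <- vapply(seq_len(span), function(cix) {
      col <- colBase[, cix]
      col <- col[!is.na(col)]
      tab <- table(col)
      mx <- names(tab)[tab == max(tab)]
      if (length(mx) == 1L) return(mx)
      # tie: first (longest) contributor whose base is among the tied ones
      colAll <- colBase[, cix]
      colAll[!is.na(colAll) & colAll %in% mx][1L]
    }, character(1))
    out[root] <- paste(cons, collapse = "")
    reportRows[[length(reportRows) + 1L]] <- data.frame(
      component = cc, members = paste(memb, collapse = ","), merged = TRUE,
      stringsAsFactors = FALSE)
  }
  list(contigs = out, report = do.call(rbind, reportRows))
}
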