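# Threshold-based SNP/indel calling from pileups, VCF-style indel
# normalization, and the depth / allele-count / minor-allele-frequency
# filter chain.

# Canonical VCF representation: trim shared trailing/leading bases and
# left-align the indel, keeping one anchor base before the event.
vcfNormalizeIndel <- function(seq, pos, ref, alt) {
  chs <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
  repeat {
    changed <- FALSE
    # drop shared trailing base
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    # left-extend when one allele is exhausted down to the anchor and the
    # event can slide left
    if ((nchar(ref) == 1L || nchar(alt) == 1L) && pos > 0L &&
        substr(ref, nchar(ref), nchar(ref)) ==
        substr(alt, nchar(alt), nchar(alt))) {
      prev <- substr(seq, pos, pos)  # base at 0-based pos-1
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # drop shared leading bases beyond the anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

emptyVariants <- function() {
  data.frame(contigId = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0), depth = integer(0),
             altCount = integer(0), maf = numeric(0),
             stringsAsFactors = FALSE)
}

#' Call unfiltered variants from pileups
#'
#' A site is emitted whenever any non-reference allele — an alternative
#' base, an anchored insertion string, or an anchored deletion — is
#' supported by at least one read. SNP REF/ALT are single bases; indels
#' are reported left-aligned in VCF-anchored form (REF/ALT share the
#' anchor base, POS points at it). The minor allele frequency is
#' `min(altCount, depth - altCount) / depth` at the site.
#'
#' @param pileup Result of [buildPileup()].
#' @return Variant table: `contigId`, `pos` (0-based anchor), `ref`,
#'   `alt`, `vtype` (`SNP`/`INS`/`DEL`), `depth`, `altCount`, `maf`,
#'   ordered by contig then position.
#' @export
callVariants <- function(pileup) {
  rows <- list()
  for (p in pileup) {
    seq <- paste(p$ref, collapse = "")
    depth <- colSums(p$mat) + p$del
    covered <- which(depth > 0L)
    for (cix in covered) {
      refBase <- p$ref[cix]
      for (b in rownames(p$mat)) {
        n <- p$mat[b, cix]
        if (b == refBase || n == 0L || b == "N") next
        rows[[length(rows) + 1L]] <- data.frame(
          contigId = p$contigId, pos = cix - 1L, ref = refBase, alt = b,
          vtype = "SNP", depth = depth[cix], altCount = n,
          stringsAsFactors = FALSE)
      }
    }
    for (k in ls(p$events)) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      anchor <- as.integer(parts[1L]); type <- parts[2L]; s <- parts[3L]
      n <- p$events[[k]]
      anchorBase <- p$ref[anchor + 1L]
      if (type == "I") {
        norm <- vcfNormalizeIndel(seq, anchor, anchorBase,
                                  paste0(anchorBase, s))
        vtype <- "INS"
      } else {
        norm <- vcfNormalizeIndel(seq, anchor, paste0(anchorBase, s),
                                  anchorBase)
        vtype <- "DEL"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contigId = p$contigId, pos = norm$pos, ref = norm$ref,
        alt = norm$alt, vtype = vtype, depth = depth[anchor + 1L],
        altCount = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyVariants())
  out <- do.call(rbind, rows)
  out$maf <- pmin(out$altCount, out$depth - out$altCount) / out$depth
  out <- out[cOrder(out$contigId, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the variant filter chain
#'
#' A variant passes when `depth >= minDepth`, `depth <= maxDepth`,
#' `altCount >= minAlt` and `maf >= minMaf` — all boundaries inclusive on
#' the passing side. Failures are labelled by the first failing rule in
#' that order (`minDepth`, `maxDepth`, `minAlt`, `minMaf`).
#'
#' @param variants Variant table from [callVariants()].
#' @param minDepth Minimum site depth. Default 6.
#' @param maxDepth Maximum site depth. Default 10000.
#' @param minAlt Minimum alternate allele count. Default 2.
#' @param minMaf Minimum minor allele frequency. Default 0.15.
#' @return The variant table with a `filter` column (`"PASS"` or the
#'   failing rule's name).
#' @export
filterVariants <- function(variants, minDepth = 6L, maxDepth = 10000L,
                           minAlt = 2L, minMaf = 0.15) {
  filter <- rep("PASS", nrow(variants))
  filter[variants$maf < minMaf] <- "minMaf"
  filter[variants$altCount < minAlt] <- "minAlt"
  filter[variants$depth > maxDepth] <- "maxDepth"
  filter[variants$depth < minDepth] <- "minDepth"
  variants$filter <- filter
  variants
}
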