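# Transcript-coordinate variant effect classification against per-contig
# gene models (5'UTR / CDS / 3'UTR from the longest ORF), with the
# controlled category vocabulary and combination summary tables.

#' Controlled vocabulary of effect categories
#' @export
effectVocabulary <- c(
  "3_prime_UTR_variant", "5_prime_UTR_variant",
  "5_prime_UTR_premature_start_codon_gain_variant",
  "initiator_codon_variant", "intergenic_region", "missense_variant",
  "synonymous_variant", "stop_gained", "stop_lost", "stop_retained_variant",
  "start_lost", "frameshift_variant", "inframe_insertion",
  "inframe_deletion", "disruptive_inframe_insertion",
  "disruptive_inframe_deletion", "chromosome_number_variation")

codonAA <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa) || is.na(aa)) "X" else aa
}

# Express a VCF-anchored variant in transcript orientation. Returns pos /
# ref / alt with the same anchoring conventions on the transcript strand.
variantToTranscript <- function(seq, pos, ref, alt, vtype, strand) {
  L <- nchar(seq)
  if (strand == "+")
    return(list(seq = seq, pos = pos, ref = ref, alt = alt))
  tSeq <- revComp(c(x = seq))[[1L]]
  if (vtype == "SNP") {
    return(list(seq = tSeq, pos = L - 1L - pos,
                ref = revComp(c(x = ref))[[1L]],
                alt = revComp(c(x = alt))[[1L]]))
  }
  if (vtype == "INS") {
    ins <- substr(alt, 2L, nchar(alt))
    tAnchor <- L - 2L - pos
    if (tAnchor < 0L) tAnchor <- 0L  # insertion at transcript 5' end
    anchorBase <- substr(tSeq, tAnchor + 1L, tAnchor + 1L)
    norm <- vcfNormalizeIndel(tSeq, tAnchor, anchorBase,
                              paste0(anchorBase, revComp(c(x = ins))[[1L]]))
  } else {
    del <- substr(ref, 2L, nchar(ref))
    len <- nchar(del)
    tAnchor <- L - 2L - pos - len
    if (tAnchor < 0L) tAnchor <- 0L
    anchorBase <- substr(tSeq, tAnchor + 1L, tAnchor + 1L)
    norm <- vcfNormalizeIndel(tSeq, tAnchor,
                              paste0(anchorBase, revComp(c(x = del))[[1L]]),
                              anchorBase)
  }
  list(seq = tSeq, pos = norm$pos, ref = norm$ref, alt = norm$alt)
}

applyEdit <- function(seq, pos, ref, alt) {
  paste0(substr(seq, 1L, pos), alt,
         substr(seq, pos + nchar(ref) + 1L, nchar(seq)))
}

classifySnpCds <- function(tSeq, tPos, alt, cs, ce, altStartCodons) {
  codonIdx <- (tPos - cs) %/% 3L
  nCodons <- (ce - cs) %/% 3L
  cStart <- cs + 3L * codonIdx
  refCodon <- substr(tSeq, cStart + 1L, cStart + 3L)
  off <- tPos - cStart
  altCodon <- refCodon
  substr(altCodon, off + 1L, off + 1L) <- alt
  refAA <- codonAA(refCodon); altAA <- codonAA(altCodon)
  cat <- if (codonIdx == 0L && refCodon == "ATG") {
    if (altCodon %in% altStartCodons) "initiator_codon_variant"
    else "start_lost"
  } else if (codonIdx == nCodons - 1L && refAA == "*") {
    if (altAA == "*") "stop_retained_variant" else "stop_lost"
  } else if (altAA == refAA) {
    "synonymous_variant"
  } else if (altAA == "*") {
    "stop_gained"
  } else {
    "missense_variant"
  }
  list(categories = cat, codonChange = c(refCodon, altCodon))
}

classifyIndelCds <- function(tSeq, tPos, ref, alt, vtype, cs, ce) {
  cats <- character(0)
  indelLen <- abs(nchar(ref) - nchar(alt))
  editStart <- tPos + 1L  # first inserted-before / deleted position
  if (vtype == "DEL") {
    delEnd <- editStart + indelLen  # half-open
    if (editStart <= cs && delEnd >= ce)
      return("chromosome_number_variation")
  }
  inframe <- indelLen %% 3L == 0L
  aligned <- (editStart - cs) %% 3L == 0L
  if (!inframe) {
    cats <- c(cats, "frameshift_variant")
  } else if (vtype == "INS") {
    cats <- c(cats, if (aligned) "inframe_insertion"
              else "disruptive_inframe_insertion")
  } else {
    cats <- c(cats, if (aligned) "inframe_deletion"
              else "disruptive_inframe_deletion")
  }
  # compound categories: initiator / terminator destroyed or created
  if (vtype == "DEL") {
    delEnd <- editStart + indelLen
    if (editStart < cs + 3L && delEnd > cs) cats <- c(cats, "start_lost")
    if (editStart < ce && delEnd > ce - 3L) cats <- c(cats, "stop_lost")
  } else {
    if (editStart > cs && editStart < cs + 3L) cats <- c(cats, "start_lost")
  }
  # a novel stop codon among the codons the edit rewrites (a codon-aligned
  # in-frame deletion rewrites none; relocating the original terminal stop
  # is not a gain)
  altSeq <- applyEdit(tSeq, tPos, ref, alt)
  jIdx <- (editStart - cs) %/% 3L
  nAltCodons <- (nchar(altSeq) - cs) %/% 3L
  novelIdx <- if (!inframe || (!aligned && vtype == "DEL")) {
    jIdx                                  # the single junction codon
  } else if (vtype == "INS") {
    jIdx:(jIdx + indelLen %/% 3L - if (aligned) 1L else 0L)
  } else integer(0)                       # aligned in-frame deletion
  novelIdx <- novelIdx[novelIdx >= 0L & novelIdx < nAltCodons]
  for (ci in novelIdx) {
    a <- substr(altSeq, cs + 3L * ci + 1L, cs + 3L * ci + 3L)
    if (nchar(a) == 3L && codonAA(a) == "*") {
      cats <- c(cats, "stop_gained")
      break
    }
  }
  unique(cats)
}

#' Classify the effect of one variant against a gene model
#'
#' The variant is mapped into transcript orientation (reverse-complemented
#' for `-`-strand gene models) and classified by region: contigs without a
#' gene model give `intergenic_region`; 5'UTR SNPs additionally gain
#' `5_prime_UTR_premature_start_codon_gain_variant` when the alternate
#' allele creates a new `ATG` wholly within the 5'UTR; CDS SNPs are
#' classified at codon level (synonymous / missense / stop gained / stop
#' lost / stop retained / start lost / initiator codon); CDS indels are
#' frameshift or (disruptive) in-frame according to length and codon
#' alignment, with compound start/stop categories when the initiator or
#' terminator codon is destroyed or a novel junction stop is created, and
#' a deletion spanning the entire CDS is a `chromosome_number_variation`.
#' An indel touching several regions collects the categories of every
#' region it touches.
#'
#' @param variant One-row variant table (see [callVariants()]).
#' @param geneModel One-row gene model ([geneModelFromOrf()]) or `NULL`.
#' @param contigSeq The contig's forward-strand sequence.
#' @param altStartCodons Character vector of alternative initiator codons
#'   for `initiator_codon_variant` (default none, so any initiator SNP is
#'   `start_lost`).
#' @return List with `categories` (subset of [effectVocabulary]) and
#'   `codonChange` (`c(ref_codon, alt_codon)` for CDS SNPs, else `NULL`).
#' @export
classifyEffect <- function(variant, geneModel, contigSeq,
                           altStartCodons = character(0)) {
  L <- nchar(contigSeq)
  if (variant$pos < 0L || variant$pos + nchar(variant$ref) > L)
    stop("variant coordinates outside contig")
  if (is.null(geneModel) || (is.data.frame(geneModel) && nrow(geneModel) == 0L))
    return(list(categories = "intergenic_region", codonChange = NULL))
  gm <- as.list(geneModel)
  tv <- variantToTranscript(contigSeq, variant$pos, variant$ref,
                            variant$alt, variant$vtype, gm$strand)
  cs <- gm$cdsStart; ce <- gm$cdsEnd
  if (variant$vtype == "SNP") {
    tPos <- tv$pos
    if (tPos < cs) {
      cats <- "5_prime_UTR_variant"
      altSeq <- applyEdit(tv$seq, tPos, tv$ref, tv$alt)
      starts <- seq_len(max(cs - 3L, 0L))  # 1-based starts of windows in UTR
      gained <- length(starts) > 0L &&
        any(substring(altSeq, starts, starts + 2L) == "ATG" &
            substring(tv$seq, starts, starts + 2L) != "ATG")
      if (gained)
        cats <- c(cats, "5_prime_UTR_premature_start_codon_gain_variant")
      return(list(categories = cats, codonChange = NULL))
    }
    if (tPos >= ce)
      return(list(categories = "3_prime_UTR_variant", codonChange = NULL))
    return(classifySnpCds(tv$seq, tPos, tv$alt, cs, ce, altStartCodons))
  }
  # indel: collect categories of every region the edit touches
  indelLen <- abs(nchar(tv$ref) - nchar(tv$alt))
  if (variant$vtype == "DEL") {
    s <- tv$pos + 1L; e <- s + indelLen  # deleted span, half-open
  } else {
    s <- tv$pos + 1L; e <- s  # insertion point
  }
  cats <- character(0)
  touchesUtr5 <- s < cs && cs > 0L
  touchesUtr3 <- e > ce || (variant$vtype == "INS" && s >= ce && ce < nchar(tv$seq))
  touchesCds <- (variant$vtype == "DEL" && s < ce && e > cs) ||
    (variant$vtype == "INS" && s > cs && s < ce)
  if (variant$vtype == "INS" && s <= cs) touchesUtr5 <- TRUE
  if (touchesUtr5) cats <- c(cats, "5_prime_UTR_variant")
  if (touchesCds)
    cats <- c(cats, classifyIndelCds(tv$seq, tv$pos, tv$ref, tv$alt,
                                     variant$vtype, cs, ce))
  if (touchesUtr3) cats <- c(cats, "3_prime_UTR_variant")
  if (!length(cats)) cats <- "intergenic_region"
  list(categories = unique(cats), codonChange = NULL)
}

#' Classify effects for a variant table
#'
#' @param variants Variant table ([callVariants()] / [filterVariants()]).
#' @param models Gene-model table ([geneModels()]).
#' @param contigs Named character vector or `DNAStringSet`.
#' @inheritParams classifyEffect
#' @return `variants` with an added list-column `effects`; each element is
#'   the [classifyEffect()] result.
#' @export
classifyEffects <- function(variants, models, contigs,
                            altStartCodons = character(0)) {
  seqs <- if (methods::is(contigs, "DNAStringSet"))
    stats::setNames(as.character(contigs), names(contigs)) else contigs
  effects <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    id <- variants$contigId[i]
    gm <- models[models$contigId == id, , drop = FALSE]
    effects[[i]] <- classifyEffect(
      variants[i, , drop = FALSE],
      if (nrow(gm)) gm[1L, , drop = FALSE] else NULL,
      seqs[[id]], altStartCodons)
  }
  variants$effects <- effects
  variants
}

#' Summarize effect annotations into a category table
#'
#' Multi-category annotations are reported as joined combinations (the
#' categories sorted and joined by `" + "`), one row per observed
#' combination, sorted alphabetically; `percent` is the share of all
#' annotations, reported to 3 decimals.
#'
#' @param annotated Variant table with an `effects` column
#'   ([classifyEffects()]), or a list of effect annotations.
#' @return data.frame with columns `type`, `count`, `percent`.
#' @export
summarizeEffects <- function(annotated) {
  effs <- if (is.data.frame(annotated)) annotated$effects else annotated
  if (!length(effs))
    return(data.frame(type = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  combos <- vapply(effs, function(e)
    paste(sort(e$categories), collapse = " + "), character(1))
  tab <- table(combos)
  out <- data.frame(type = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[cOrder(out$type), , drop = FALSE]
  out$percent <- round(100 * out$count / sum(out$count), 3L)
  rownames(out) <- NULL
  out
}
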