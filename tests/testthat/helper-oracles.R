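# Shared fixtures and independent oracles used across the suite. Oracles
# deliberately avoid the package's own code paths: brute-force scans,
# direct enumeration, or calls to reference implementations.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rcOracle <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Brute-force six-frame longest-ORF scanner: enumerate every ATG on both
# strands, walk codons to the next stop (or the last complete codon), and
# apply the documented tie-breaks.
bruteLongestOrf <- function(seq, minLenNt = 90L) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rcOracle(seq)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    atg <- which(ch == "A" & c(ch[-1L], "") == "T" &
                 c(ch[-(1:2)], "", "") == "G")
    for (a in atg) {
      p <- a
      stopAt <- NA_integer_
      while (p + 2L <= L) {
        if (paste(ch[p:(p + 2L)], collapse = "") %in% stops && p > a) {
          stopAt <- p
          break
        }
        p <- p + 3L
      }
      if (!is.na(stopAt)) {
        endNt <- stopAt + 2L
        c3 <- TRUE
      } else {
        endNt <- p - 1L
        c3 <- FALSE
      }
      span <- endNt - a + 1L
      if (span < minLenNt) next
      fstart <- if (strand == "+") a - 1L else L - endNt
      cands[[length(cands) + 1L]] <- data.frame(
        span = span, strand = strand, fstart = fstart,
        fend = fstart + span, complete3p = c3)
    }
  }
  if (!length(cands)) return(NULL)
  all <- do.call(rbind, cands)
  all[order(-all$span, all$strand != "+", all$fstart)[1L], ]
}

# Two-sided Fisher p by direct enumeration over the hypergeometric support
# using stats::dhyper.
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# All-pairs greedy clustering oracle: identity via full dynamic-programming
# alignment (Biostrings::pairwiseAlignment directly), no word prefilter.
oracleIdentity <- function(x, y) {
  if (nchar(x) > nchar(y)) { tmp <- x; x <- y; y <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  alnF <- Biostrings::pairwiseAlignment(x, y, type = "global-local",
    substitutionMatrix = sm, gapOpening = 4, gapExtension = 2)
  alnR <- Biostrings::pairwiseAlignment(rcOracle(x), y, type = "global-local",
    substitutionMatrix = sm, gapOpening = 4, gapExtension = 2)
  max(Biostrings::nmatch(alnF), Biostrings::nmatch(alnR)) / nchar(x)
}

oracleGreedyCluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (oracleIdentity(seqs[[i]], seqs[[reps[r]]]) >= threshold) {
        members[[r]] <- c(members[[r]], names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  setNames(lapply(members, sort), reps)
}

# Planted duplicate-family fixture used by the clustering checks: families
# of fixed-length sequences at a designed identity to their base.
plantFamiliesFixture <- function(nFamilies = 10L, familySize = 5L,
                                 len = 500L, identity = 0.99, seed = 42L) {
  set.seed(seed)
  seqs <- character(0)
  truth <- list()
  for (f in seq_len(nFamilies)) {
    base <- randSeq(len)
    baseId <- sprintf("fam%02d_a", f)
    seqs[baseId] <- base
    fam <- baseId
    nSub <- round((1 - identity) * len)
    for (v in seq_len(familySize - 1L)) {
      ch <- strsplit(base, "", fixed = TRUE)[[1L]]
      pos <- sample.int(len, nSub)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      vid <- sprintf("fam%02d_%s", f, letters[v + 1L])
      seqs[vid] <- paste(ch, collapse = "")
      fam <- c(fam, vid)
    }
    truth[[f]] <- sort(fam)
  }
  list(seqs = seqs, families = truth)
}

# Tiled-contig fixture: one source sequence cut into overlapping pieces.
tileFixture <- function(sourceLen = 1200L, cuts = c(0, 400, 800),
                        pieceLen = 500L, seed = 7L) {
  set.seed(seed)
  src <- randSeq(sourceLen)
  pieces <- setNames(
    vapply(seq_along(cuts), function(i)
      substr(src, cuts[i] + 1L, min(cuts[i] + pieceLen, sourceLen)),
      character(1)),
    sprintf("tile%d", seq_along(cuts)))
  list(source = src, pieces = pieces)
}

toyContig <- "CCATGAAATAGCC"
toyModel <- function() geneModelFromOrf(
  "toy", 13L, findLongestOrf(toyContig, minLenNt = 9L))

# Hand-derived per-position truth for every possible SNP on the toy contig
# (5'UTR = CC, CDS = ATG AAA TAG, 3'UTR = CC).
toySnpTruth <- function(pos, alt) {
  if (pos <= 1L) return("5_prime_UTR_variant")
  if (pos >= 11L) return("3_prime_UTR_variant")
  if (pos <= 4L) return("start_lost")              # ATG initiator
  if (pos == 5L) return(if (alt == "T") "stop_gained" else "missense_variant")
  if (pos == 6L) return("missense_variant")        # AAA -> A_A all missense
  if (pos == 7L) return(if (alt == "G") "synonymous_variant"
                        else "missense_variant")   # AAG is still Lys
  if (pos %in% c(8L, 9L)) return("stop_lost")      # TAG broken
  if (alt == "A") "stop_retained_variant" else "stop_lost"  # pos 10: TAA
}

mkVar <- function(contigId, pos, ref, alt, vtype = "SNP", depth = 20L,
                  altCount = 10L) {
  data.frame(contigId = contigId, pos = pos, ref = ref, alt = alt,
             vtype = vtype, depth = depth, altCount = altCount,
             maf = min(altCount, depth - altCount) / depth,
             stringsAsFactors = FALSE)
}
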