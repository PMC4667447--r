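# Deterministic synthetic-data generation with planted ground truth: source
# transcripts with known gene models, sequencing reads with known origins,
# planted duplicate families, antisense chimeras and variant sites. One
# parent seed fans out to fixed per-stage child seeds so stages can be
# regenerated independently.

BASES <- c("A", "C", "G", "T")
stopCodons <- c("TAA", "TAG", "TGA")

randomCodingSeq <- function(nCodons) {
  codons <- character(nCodons)
  i <- 1L
  while (i <= nCodons) {
    cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
    if (cd %in% stopCodons) next
    codons[i] <- cd
    i <- i + 1L
  }
  paste(codons, collapse = "")
}

#' Simulate a transcriptome with known gene models
#'
#' Each transcript is built as 5'UTR + CDS + 3'UTR with the CDS an
#' `ATG`-initiated, stop-terminated open reading frame free of internal
#' stops; transcripts are rejection-sampled until the designed ORF is the
#' unique longest ORF, so [findLongestOrf()] must recover the designed
#' model exactly.
#'
#' @param n Number of transcripts (`>= 1`).
#' @param lengthRange Total transcript length range. Default `c(400, 700)`.
#' @param utrRange Per-UTR length range. Default `c(30, 80)`.
#' @param gc GC content of the UTRs. Default 0.5.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return List with `transcripts` (named character vector, ids
#'   `t01, t02, ...`) and `truth` (data.frame `id`, `length`, `utr5Len`,
#'   `cdsLen`, `utr3Len`).
#' @export
makeTranscriptome <- function(n, lengthRange = c(400L, 700L),
                              utrRange = c(30L, 80L), gc = 0.5, seed = 1L) {
  stopifnot(n >= 1L)
  if (lengthRange[1L] < 2L * utrRange[2L] + 90L)
    stop("infeasible constraints: transcripts too short for the designed ORF")
  withSeed(childSeed(seed, 101L), {
    ids <- sprintf("t%02d", seq_len(n))
    seqs <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        len <- sample(lengthRange[1L]:lengthRange[2L], 1L)
        u5 <- sample(utrRange[1L]:utrRange[2L], 1L)
        u3 <- sample(utrRange[1L]:utrRange[2L], 1L)
        cdsLen <- len - u5 - u3
        cdsLen <- cdsLen - (cdsLen %% 3L)
        if (cdsLen < 90L) next
        len <- u5 + cdsLen + u3
        cds <- paste0("ATG", randomCodingSeq(cdsLen / 3L - 2L),
                      sample(stopCodons, 1L))
        tr <- paste0(randomDna(u5, gc), cds, randomDna(u3, gc))
        orf <- findLongestOrf(tr, minLenNt = 90L)
        if (!is.null(orf) && orf$strand == "+" && orf$start == u5 &&
            orf$end == u5 + cdsLen)
          break
      }
      seqs[i] <- tr
      truth[[i]] <- data.frame(id = ids[i], length = len, utr5Len = u5,
                               cdsLen = cdsLen, utr3Len = u3,
                               stringsAsFactors = FALSE)
    }
    list(transcripts = stats::setNames(seqs, ids),
         truth = do.call(rbind, truth))
  })
}

mutateBases <- function(s, positions) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    alt <- sample(setdiff(BASES, ch[p]), 1L)
    ch[p] <- alt
  }
  paste(ch, collapse = "")
}

#' Simulate reads from transcripts with known origins
#'
#' Uniform start positions, independent substitution errors at
#' `errorRate`, `N` injections at `nRate`; qualities are constant `"I"`
#' (Phred 40). The number of reads per transcript is
#' `max(1, round(depth * length / readLen))`, recorded as the designed
#' count. Transcripts shorter than `readLen` are skipped with a warning.
#'
#' @param transcripts Named character vector.
#' @param depth Target fold-coverage per transcript. Default 10.
#' @param readLen Read length. Default 80.
#' @param errorRate Per-base substitution probability. Default 0.
#' @param nRate Per-base probability of replacing the call with `N`.
#'   Default 0.
#' @param libId Library id used as read-name prefix. Default `"lib1"`.
#' @param seed Integer seed.
#' @return List with `reads` (read table) and `truth` (data.frame
#'   `readId`, `transcript`, `start`) and `designedCounts` (named integer
#'   vector per transcript).
#' @export
makeReads <- function(transcripts, depth = 10, readLen = 80L,
                      errorRate = 0, nRate = 0, libId = "lib1", seed = 1L) {
  stopifnot(depth >= 1)
  withSeed(childSeed(seed, 211L), {
    rows <- list(); tr <- list()
    counts <- stats::setNames(integer(length(transcripts)),
                              names(transcripts))
    for (id in names(transcripts)) {
      s <- transcripts[[id]]
      L <- nchar(s)
      if (L < readLen) {
        warning("transcript ", id, " shorter than readLen; skipped")
        next
      }
      nReads <- max(1L, as.integer(round(depth * L / readLen)))
      counts[id] <- nReads
      starts <- sample.int(L - readLen + 1L, nReads, replace = TRUE) - 1L
      for (j in seq_len(nReads)) {
        b <- substr(s, starts[j] + 1L, starts[j] + readLen)
        if (errorRate > 0) {
          errPos <- which(stats::runif(readLen) < errorRate)
          if (length(errPos)) b <- mutateBases(b, errPos)
        }
        if (nRate > 0) {
          nPos <- which(stats::runif(readLen) < nRate)
          if (length(nPos)) {
            ch <- strsplit(b, "", fixed = TRUE)[[1L]]
            ch[nPos] <- "N"
            b <- paste(ch, collapse = "")
          }
        }
        rid <- sprintf("%s_%s_r%04d", libId, id, j)
        rows[[length(rows) + 1L]] <- b
        tr[[length(tr) + 1L]] <- data.frame(
          readId = rid, transcript = id, start = starts[j],
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, tr)
    reads <- data.frame(id = truth$readId, bases = unlist(rows),
                        quals = strrep("I", readLen),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, designedCounts = counts)
  })
}

#' Plant duplicate families among transcripts
#'
#' For each selected base transcript, `familySize - 1` variants are
#' created by taking a window of `windowFrac` of its length (emulating the
#' partial re-assemblies other k-mers produce, and keeping the full-length
#' base the longest family member) and substituting a `1 - identity`
#' fraction of its positions, so a clustering run at a threshold just
#' below `identity` must recover each family exactly with the base as
#' representative.
#'
#' @param transcripts Named character vector.
#' @param nFamilies Number of base transcripts to expand (the first
#'   `nFamilies` in order). Default all.
#' @param familySize Total family size including the base (`>= 2`).
#' @param identity Designed variant-to-base identity in (0.8, 1].
#' @param windowFrac Variant length as a fraction of the base length, in
#'   (0, 1]. Default 0.9.
#' @param seed Integer seed.
#' @return List with `sequences` (bases + variants, variants named
#'   `<baseId>_dup<k>`) and `truth` (data.frame `id`, `family`).
#' @export
plantDuplicates <- function(transcripts, nFamilies = length(transcripts),
                            familySize = 2L, identity = 0.99,
                            windowFrac = 0.9, seed = 1L) {
  stopifnot(identity > 0.8, identity <= 1, familySize >= 2L,
            windowFrac > 0, windowFrac <= 1)
  withSeed(childSeed(seed, 307L), {
    out <- transcripts
    truth <- data.frame(id = names(transcripts),
                        family = names(transcripts),
                        stringsAsFactors = FALSE)
    for (id in names(transcripts)[seq_len(nFamilies)]) {
      s <- transcripts[[id]]
      for (k in seq_len(familySize - 1L)) {
        wLen <- max(1L, as.integer(round(windowFrac * nchar(s))))
        wStart <- sample.int(nchar(s) - wLen + 1L, 1L)
        v <- substr(s, wStart, wStart + wLen - 1L)
        nSub <- as.integer(round((1 - identity) * wLen))
        if (nSub > 0L) v <- mutateBases(v, sample.int(wLen, nSub))
        vid <- sprintf("%s_dup%d", id, k)
        out[vid] <- v
        truth <- rbind(truth, data.frame(id = vid, family = id,
                                         stringsAsFactors = FALSE))
      }
    }
    list(sequences = out, truth = truth)
  })
}

#' Plant antisense chimeras
#'
#' A chimera is the concatenation of a transcript with the reverse
#' complement of its leading portion (`portion` of its length; the default
#' 1 mirrors a full antisense duplication), the artifact an assembler
#' produces when it joins sense and antisense paths. The true junction is
#' the transcript length.
#'
#' @param transcripts Named character vector.
#' @param n Number of chimeras (taken from the first transcripts).
#'   Default 1.
#' @param portion Fraction of the transcript reverse-complemented into the
#'   second half, in (0, 1]. Default 1.
#' @param seed Integer seed (reserved for future randomized selection).
#' @return List with `sequences` (chimeric contigs named
#'   `chimera_<baseId>`) and `truth` (data.frame `id`, `base`,
#'   `junction`).
#' @export
plantChimeras <- function(transcripts, n = 1L, portion = 1.0, seed = 1L) {
  stopifnot(n >= 1L, n <= length(transcripts), portion > 0, portion <= 1)
  ids <- names(transcripts)[seq_len(n)]
  seqs <- character(0)
  rows <- list()
  for (id in ids) {
    s <- transcripts[[id]]
    L <- nchar(s)
    p <- max(1L, as.integer(round(portion * L)))
    chim <- paste0(s, revComp(c(x = substr(s, 1L, p)))[[1L]])
    cid <- paste0("chimera_", id)
    seqs[cid] <- chim
    rows[[length(rows) + 1L]] <- data.frame(id = cid, base = id,
                                            junction = L,
                                            stringsAsFactors = FALSE)
  }
  list(sequences = seqs, truth = do.call(rbind, rows))
}

#' Plant variant sites on transcripts
#'
#' Chooses `nSites` positions per transcript (uniformly, away from the
#' first/last `margin` bases so reads can span them) with a random
#' alternate allele at the designed minor allele frequency.
#'
#' @param transcripts Named character vector.
#' @param nSites Variant sites per transcript. Default 2.
#' @param maf Designed alternate allele frequency in (0, 1). Default 0.3.
#' @param margin Distance from transcript ends to avoid. Default 20.
#' @param seed Integer seed.
#' @return data.frame `transcript`, `pos` (0-based), `ref`, `alt`, `maf`.
#' @export
plantVariants <- function(transcripts, nSites = 2L, maf = 0.3,
                          margin = 20L, seed = 1L) {
  stopifnot(maf > 0, maf < 1)
  withSeed(childSeed(seed, 401L), {
    rows <- list()
    for (id in names(transcripts)) {
      s <- transcripts[[id]]
      L <- nchar(s)
      pool <- margin:(L - margin - 1L)
      pos <- sort(sample(pool, nSites))
      for (p in pos) {
        ref <- substr(s, p + 1L, p + 1L)
        alt <- sample(setdiff(BASES, ref), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = id, pos = p, ref = ref, alt = alt, maf = maf,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Apply planted variant alleles to simulated reads
#'
#' Each read covering a planted site carries the alternate allele with
#' probability equal to the site's designed frequency (independent
#' Bernoulli draws), emulating reads drawn from a polymorphic population.
#'
#' @param sim Result of [makeReads()] (zero-error recommended).
#' @param variantTruth Result of [plantVariants()].
#' @param seed Integer seed.
#' @return `sim` with mutated `reads` and an added `alleleDraws` count
#'   (data.frame `transcript`, `pos`, `altReads`, `covering`).
#' @export
applyVariantAlleles <- function(sim, variantTruth, seed = 1L) {
  withSeed(childSeed(seed, 503L), {
    reads <- sim$reads
    truth <- sim$truth
    readLen <- nchar(reads$bases[1L])
    draws <- list()
    for (v in seq_len(nrow(variantTruth))) {
      vt <- variantTruth[v, ]
      covering <- which(truth$transcript == vt$transcript &
                        truth$start <= vt$pos &
                        truth$start + readLen > vt$pos)
      isAlt <- stats::runif(length(covering)) < vt$maf
      for (t in which(isAlt)) {
        ri <- covering[t]
        off <- vt$pos - truth$start[ri]
        substr(reads$bases[ri], off + 1L, off + 1L) <- vt$alt
      }
      draws[[v]] <- data.frame(transcript = vt$transcript, pos = vt$pos,
                               altReads = sum(isAlt),
                               covering = length(covering),
                               stringsAsFactors = FALSE)
    }
    sim$reads <- reads
    sim$alleleDraws <- do.call(rbind, draws)
    sim
  })
}

#' Smoke-scale synthetic study
#'
#' The fixed small-study configuration used for end-to-end testing: 20
#' transcripts, one sample with two libraries of zero-error reads at 10x
#' depth, two planted duplicate families (one extra 99%-identity variant
#' each) and one full antisense chimera. With error-free reads the
#' pipeline must recover exactly the planted transcript set (up to
#' reverse complement) and the designed per-library counts.
#'
#' @param seed Integer seed.
#' @return List with `truth`, `transcripts`, `assembly` (the contig set
#'   emulating an assembler's output, Oases-style ids), `reads` (named
#'   list of per-library read tables), `designedCounts` (transcripts x
#'   libraries matrix).
#' @export
smokePreset <- function(seed = 1L) {
  tx <- makeTranscriptome(20L, seed = seed)
  dup <- plantDuplicates(tx$transcripts, nFamilies = 2L, familySize = 2L,
                         identity = 0.99, seed = seed)
  chi <- plantChimeras(tx$transcripts, n = 1L, portion = 1.0, seed = seed)
  assembly <- c(dup$sequences, chi$sequences)
  # Oases-style ids: one locus per contig
  names(assembly) <- sprintf(
    "Locus_%d_Transcript_1/1_Confidence_1.000_Length_%d|%s",
    seq_along(assembly), nchar(assembly), names(assembly))
  libs <- c("lib1", "lib2")
  reads <- list(); designed <- NULL
  for (li in seq_along(libs)) {
    sim <- makeReads(tx$transcripts, depth = 10, readLen = 80L,
                     errorRate = 0, nRate = 0, libId = libs[li],
                     seed = childSeed(seed, li))
    reads[[libs[li]]] <- sim$reads
    designed <- cbind(designed, sim$designedCounts)
  }
  colnames(designed) <- libs
  list(truth = list(transcripts = tx$truth, duplicates = dup$truth,
                    chimeras = chi$truth),
       transcripts = tx$transcripts, assembly = assembly, reads = reads,
       designedCounts = designed)
}
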