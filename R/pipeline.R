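# The two-pass pipeline: per-library read cleansing, per-sample assembly
# merging (locus selection, chimera handling, dedup, overlap merge, length
# and RPM filters, indel correction), cross-sample meta-assembly (renaming,
# longest-ORF clustering, final dedup, RPM filter), quantification, variant
# calling/filtering and effect classification.

#' Default pipeline parameters
#'
#' Returns the full set of tunables with their defaults: thresholds of the
#' clustering, overlap, length, RPM and variant filter stages, mapper and
#' pileup settings, and read-cleansing options.
#'
#' @return Named list of parameters.
#' @export
pipelineParams <- function() {
  list(
    normalize = FALSE, normK = 25L, normMaxCoverage = 30L,
    keepAtHalf = FALSE,
    locusKey = "len,depth",
    chimeraSeedLen = 12L, chimeraMinMatch = 60L, chimeraMinIdentity = 0.95,
    minLen = 200L,
    dedupIdentity = 0.98,
    overlapMinLen = 60L, overlapIdentity = 0.96, overlapSeedLen = 16L,
    orfMinLen = 90L, orfIdentity = 0.90, orfLevel = "aa",
    finalIdentity = 0.95,
    seedLen = 21L, maxMismatchRate = 0.04,
    minMapq = 30L, maxPileupDepth = 10000L,
    correctionMinDepth = 4L, correctionMajority = 0.5,
    rpmThreshold = 2.0, rpmDenominator = "cleaned",
    varMinDepth = 6L, varMaxDepth = 10000L, varMinAlt = 2L,
    varMinMaf = 0.15,
    altStartCodons = character(0)
  )
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and
#' blank lines ignored. Unknown keys are an error. Values are coerced to
#' the type of the corresponding default from [pipelineParams()].
#'
#' @param path Configuration file path.
#' @return Parameter list (defaults overridden by the file).
#' @export
readPipelineConfig <- function(path) {
  params <- pipelineParams()
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(params)) stop("unknown config key: ", key)
    proto <- params[[key]]
    params[[key]] <- if (is.logical(proto)) as.logical(val)
      else if (is.integer(proto)) as.integer(val)
      else if (is.numeric(proto)) as.numeric(val)
      else if (length(proto) != 1L) strsplit(val, ",", fixed = TRUE)[[1L]]
      else val
  }
  params
}

asSeqs <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) x <- readFasta(x)
  if (methods::is(x, "DNAStringSet"))
    stats::setNames(as.character(x), names(x)) else x
}

asReadTable <- function(x) {
  if (is.character(x) && length(x) == 1L) readFastq(x) else x
}

#' Run the full meta-assembly pipeline
#'
#' Executes, in order: per-library cleansing (and optional digital
#' normalization); per sample — per-assembly locus representative
#' selection, pooling of the k-mer assemblies, antisense-chimera
#' split/removal, nucleotide dedup clustering, overlap merging, minimum
#' length filter, read remapping with spurious-indel correction and a
#' reads-per-million filter; across samples — sample-prefixed renaming,
#' longest-ORF clustering at protein level, final nucleotide dedup, global
#' remapping with an RPM filter; then quantification into the count
#' matrix, variant calling + filtering, and effect classification with
#' summary tables. Fully deterministic: rerunning on the same inputs and
#' parameters reproduces identical artifacts.
#'
#' @param samples Named list (sample label -> list) with elements
#'   `assemblies` (named list: assembly label -> named character vector /
#'   `DNAStringSet` / FASTA path, Oases-style headers recognized) and
#'   `libraries` (named list: library id -> list with `reads` (read table
#'   or FASTQ path) and optional `reads2` for paired input).
#' @param outDir Optional artifacts directory (created if needed); when
#'   given, writes contigs FASTA, counts TSV, VCF, gene models, effect
#'   summaries, chimera report, stage log and an md5 manifest.
#' @param params Parameter list from [pipelineParams()] /
#'   [readPipelineConfig()].
#' @return List with `contigs` (final named character vector), `counts`
#'   (\linkS4class{ContigCounts}), `variants` (filtered, annotated),
#'   `models`, `snpSummary`, `indelSummary`, `chimeraReport`,
#'   `cleanseReports`, `stageLog` (data.frame of per-stage in/out counts).
#' @export
runPipeline <- function(samples, outDir = NULL, params = pipelineParams()) {
  log <- list()
  note <- function(stage, nin, nout)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = nin,
                                           n_out = nout,
                                           stringsAsFactors = FALSE)
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop("samples must be a uniquely named list")

  ## stage 1: cleanse reads per library
  cleaned <- list()       # lib -> read table
  cleanedTotals <- c()    # lib -> cleaned read count
  libSample <- c()        # lib -> sample
  cleanseReports <- list()
  for (s in names(samples)) {
    libs <- samples[[s]]$libraries
    if (is.null(libs) || is.null(names(libs)))
      stop("sample ", s, " has no named libraries")
    for (lib in names(libs)) {
      spec <- libs[[lib]]
      r1 <- asReadTable(spec$reads)
      r2 <- if (!is.null(spec$reads2)) asReadTable(spec$reads2) else NULL
      cl <- cleanseReads(r1, r2, keepAtHalf = isTRUE(params$keepAtHalf))
      rd <- if (is.null(r2)) cl$reads else rbind(cl$reads, cl$reads2)
      if (isTRUE(params$normalize)) {
        nm <- kmerNormalize(rd, params$normK, params$normMaxCoverage)
        cl$report <- c(cl$report, normalized_out = unname(nm$report["kept"]))
        rd <- nm$reads
      }
      cleaned[[lib]] <- rd
      cleanedTotals[lib] <- nrow(rd)
      libSample[lib] <- s
      cleanseReports[[lib]] <- cl$report
      note(paste0("cleanse:", lib), nrow(r1) + if (is.null(r2)) 0L else
        nrow(r2), nrow(rd))
    }
  }

  ## stage 2: per-sample assembly merging
  perSample <- list()
  chimeraReports <- list()
  for (s in names(samples)) {
    pooled <- character(0)
    for (lab in names(samples[[s]]$assemblies)) {
      seqs <- asSeqs(samples[[s]]$assemblies[[lab]])
      meta <- parseOasesHeader(names(seqs))
      seqs <- withCallingHandlers(
        locusRepresentatives(seqs, meta, key = params$locusKey),
        warning = function(w) invokeRestart("muffleWarning"))
      names(seqs) <- paste0(lab, ":", names(seqs))
      pooled <- c(pooled, seqs)
    }
    note(paste0("locus_select:", s),
         sum(lengths(lapply(samples[[s]]$assemblies, asSeqs))), length(pooled))
    chim <- processChimeras(pooled, params$chimeraSeedLen,
                            params$chimeraMinMatch,
                            params$chimeraMinIdentity, params$minLen)
    chimeraReports[[s]] <- cbind(sample = s, chim$report)
    note(paste0("chimera:", s), length(pooled), length(chim$contigs))
    cl <- greedyCluster(chim$contigs, params$dedupIdentity, level = "nt")
    dedup <- chim$contigs[representatives(cl)]
    note(paste0("dedup:", s), length(chim$contigs), length(dedup))
    edges <- findContigOverlaps(dedup, params$overlapMinLen,
                                params$overlapIdentity,
                                params$overlapSeedLen)
    mg <- mergeOverlapping(dedup, edges)
    note(paste0("overlap_merge:", s), length(dedup), length(mg$contigs))
    flt <- lengthFilter(mg$contigs, params$minLen)
    note(paste0("length_filter:", s), length(mg$contigs), length(flt))
    contigs <- stats::setNames(as.character(flt), names(flt))
    # remap the sample's own reads, correct indels, RPM-filter
    sampleLibs <- names(libSample)[libSample == s]
    sampleReads <- do.call(rbind, cleaned[sampleLibs])
    aln <- mapReads(sampleReads, contigs, params$seedLen,
                    params$maxMismatchRate)
    pil <- buildPileup(aln, contigs, params$minMapq, params$maxPileupDepth)
    corr <- correctContigs(contigs, pil, params$correctionMinDepth,
                           params$correctionMajority)
    contigs <- corr$contigs
    if (nrow(corr$edits)) {
      aln <- mapReads(sampleReads, contigs, params$seedLen,
                      params$maxMismatchRate)
    }
    denom <- if (params$rpmDenominator == "cleaned")
      sum(cleanedTotals[sampleLibs]) else max(nrow(aln), 1L)
    mapped <- table(factor(aln$contigId, levels = names(contigs)))
    keep <- rpmFilter(as.integer(mapped), denom, params$rpmThreshold)
    contigs <- contigs[keep]
    note(paste0("rpm_filter:", s), length(keep), length(contigs))
    perSample[[s]] <- contigs
  }

  ## stage 3: cross-sample meta-assembly
  merged <- mergeSamples(perSample)
  note("sample_merge", sum(lengths(perSample)), length(merged))
  orfs <- longestOrfTable(merged, params$orfMinLen)
  hasOrf <- orfs$orfLen > 0L
  withOrf <- orfs$contigId[hasOrf]
  noOrf <- orfs$contigId[!hasOrf]
  if (length(withOrf)) {
    level <- params$orfLevel
    clSeqs <- if (level == "aa")
      stats::setNames(orfs$protein[hasOrf], withOrf)
    else {
      # nucleotide ORF sub-sequences
      stats::setNames(vapply(withOrf, function(id)
        substr(merged[[id]], orfs$start[orfs$contigId == id] + 1L,
               orfs$end[orfs$contigId == id]), character(1)), withOrf)
    }
    cl <- greedyCluster(clSeqs, params$orfIdentity, level = level)
    reps <- selectByLongestOrf(
      cl, stats::setNames(orfs$orfLen, orfs$contigId), nchar(merged))
    selected <- c(merged[reps], merged[noOrf])
  } else selected <- merged
  note("orf_cluster", length(merged), length(selected))
  clF <- greedyCluster(selected, params$finalIdentity, level = "nt")
  finalContigs <- selected[representatives(clF)]
  note("final_dedup", length(selected), length(finalContigs))

  ## stage 4: global remap + RPM + count matrix
  perLibAln <- lapply(cleaned, function(rd)
    mapReads(rd, finalContigs, params$seedLen, params$maxMismatchRate))
  pooledCounts <- rowSums(vapply(perLibAln, function(a)
    as.integer(table(factor(a$contigId, levels = names(finalContigs)))),
    integer(length(finalContigs))))
  denom <- if (params$rpmDenominator == "cleaned") sum(cleanedTotals)
           else max(sum(vapply(perLibAln, nrow, integer(1))), 1L)
  keep <- rpmFilter(pooledCounts, denom, params$rpmThreshold)
  finalContigs <- finalContigs[keep]
  note("final_rpm_filter", length(keep), length(finalContigs))
  perLibAln <- lapply(perLibAln, function(a)
    a[a$contigId %in% names(finalContigs), , drop = FALSE])
  counts <- buildCountMatrix(perLibAln, names(finalContigs), cleanedTotals)

  ## stage 5: variants and effects
  allAln <- do.call(rbind, c(perLibAln, list(make.row.names = FALSE)))
  pil <- buildPileup(allAln, finalContigs, params$minMapq,
                     params$maxPileupDepth)
  variants <- callVariants(pil)
  variants <- filterVariants(variants, params$varMinDepth,
                             params$varMaxDepth, params$varMinAlt,
                             params$varMinMaf)
  models <- geneModels(finalContigs, params$orfMinLen)
  variants <- classifyEffects(variants, models, finalContigs,
                              params$altStartCodons)
  pass <- variants[variants$filter == "PASS", , drop = FALSE]
  snpSummary <- summarizeEffects(pass[pass$vtype == "SNP", , drop = FALSE])
  indelSummary <- summarizeEffects(pass[pass$vtype != "SNP", , drop = FALSE])
  note("variants", nrow(variants), nrow(pass))

  stageLog <- do.call(rbind, log)
  chimeraReport <- do.call(rbind, chimeraReports)
  result <- list(contigs = finalContigs, counts = counts,
                 variants = variants, models = models,
                 snpSummary = snpSummary, indelSummary = indelSummary,
                 chimeraReport = chimeraReport,
                 cleanseReports = cleanseReports, stageLog = stageLog)
  if (!is.null(outDir)) writePipelineArtifacts(result, outDir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' Writes the final contig FASTA, count matrix TSV, variant VCF, gene
#' model TSV (1-based inclusive intervals on output), SNP/indel effect
#' summary TSVs, chimera report, stage log and a `manifest.json` with md5
#' checksums of every artifact. Outputs contain no timestamps, so a rerun
#' with identical inputs is byte-identical.
#'
#' @param result A [runPipeline()] result.
#' @param outDir Output directory.
#' @return `outDir`, invisibly.
#' @export
writePipelineArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outDir, f)
  writeFasta(result$contigs, fp("contigs.fasta"))
  writeCountsTsv(result$counts, fp("count_matrix.tsv"))
  writeVcfFile(result$variants, result$contigs, fp("variants.vcf"))
  gm <- result$models
  gmOut <- data.frame(contig = gm$contigId, strand = gm$strand,
                      utr5_start = to1based(gm$utr5Start), utr5_end = gm$utr5End,
                      cds_start = to1based(gm$cdsStart), cds_end = gm$cdsEnd,
                      utr3_start = to1based(gm$utr3Start), utr3_end = gm$utr3End)
  utils::write.table(gmOut, fp("gene_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$snpSummary, fp("snp_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$indelSummary, fp("indel_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$chimeraReport, fp("chimera_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$stageLog, fp("stage_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- as.list(stats::setNames(unname(sums), files))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(outDir)
}
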