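# VCF 4.2 output (and a matching reader for round-trips). Internal variant
# coordinates are 0-based; POS on the VCF surface is 1-based. Indels are
# VCF-anchored: REF/ALT share a leading anchor base and POS points at it.

vcfInfoString <- function(variants) {
  info <- sprintf("DP=%d;AC=%d;MAF=%.6g;TYPE=%s",
                  variants$depth, variants$altCount, variants$maf,
                  variants$vtype)
  if ("effects" %in% names(variants)) {
    eff <- vapply(seq_len(nrow(variants)), function(i) {
      e <- variants$effects[[i]]
      if (is.null(e) || !length(e$categories)) return("")
      sprintf(";EFF=%s|%s", paste(e$categories, collapse = ","),
              if (is.null(e$codonChange)) "" else
                paste(e$codonChange, collapse = ">"))
    }, character(1))
    info <- paste0(info, eff)
  }
  info
}

#' Write variants as VCF 4.2
#'
#' One record per variant; `INFO` carries read depth (`DP`), alternate
#' allele count (`AC`), minor allele frequency (`MAF`), variant type
#' (`TYPE`) and, when effect annotations are attached, an
#' `EFF=<category,...>|<ref_codon>ALT<alt_codon>` field. No date line is
#' written so outputs are byte-reproducible.
#'
#' @param variants Variant table from [callVariants()] /
#'   [filterVariants()]; optionally annotated by [classifyEffects()].
#' @param contigs Reference contigs (named character or `DNAStringSet`) for
#'   `##contig` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcfFile <- function(variants, contigs, path) {
  lens <- if (methods::is(contigs, "DNAStringSet"))
    Biostrings::width(contigs) else nchar(contigs)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), lens),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=EFF,Number=.,Type=String,Description=\"Effect categories|codon change\">",
    "##FILTER=<ID=minDepth,Description=\"depth below minimum\">",
    "##FILTER=<ID=maxDepth,Description=\"depth above maximum\">",
    "##FILTER=<ID=minAlt,Description=\"alternate allele count below minimum\">",
    "##FILTER=<ID=minMaf,Description=\"minor allele frequency below minimum\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants)) {
    filt <- if ("filter" %in% names(variants)) variants$filter else "."
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                    variants$contigId, to1based(variants$pos),
                    variants$ref, variants$alt, filt,
                    vcfInfoString(variants))
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by [writeVcfFile()]
#'
#' Restores the variant table (without effect annotations, which remain in
#' the `EFF` string column when present).
#'
#' @param path Path to an uncompressed VCF file.
#' @return Variant table with columns `contigId`, `pos` (0-based), `ref`,
#'   `alt`, `depth`, `altCount`, `maf`, `vtype`, `filter`, `eff`.
#' @export
readVcfFile <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(contigId = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), altCount = integer(0),
                      maf = numeric(0), vtype = character(0),
                      filter = character(0), eff = character(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  getInfo <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  info <- vapply(f, `[`, character(1), 8L)
  data.frame(
    contigId = vapply(f, `[`, character(1), 1L),
    pos = to0based(vapply(f, function(x) as.integer(x[2L]), integer(1))),
    ref = vapply(f, `[`, character(1), 4L),
    alt = vapply(f, `[`, character(1), 5L),
    depth = vapply(info, function(i) as.integer(getInfo(i, "DP")), integer(1),
                   USE.NAMES = FALSE),
    altCount = vapply(info, function(i) as.integer(getInfo(i, "AC")),
                      integer(1), USE.NAMES = FALSE),
    maf = vapply(info, function(i) as.numeric(getInfo(i, "MAF")), numeric(1),
                 USE.NAMES = FALSE),
    vtype = vapply(info, function(i) getInfo(i, "TYPE"), character(1),
                   USE.NAMES = FALSE),
    filter = vapply(f, `[`, character(1), 7L),
    eff = vapply(info, function(i) getInfo(i, "EFF"), character(1),
                 USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
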