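# Shared internal helpers: coordinate conventions, reverse complement on
# character vectors, deterministic child seeds for the simulators.

#' @import methods
#' @importFrom stats median rbinom runif p.adjust setNames dhyper
#' @importFrom utils read.delim write.table head tail
NULL

# All internal coordinates are 0-based half-open; VCF/SAM surfaces are 1-based.
# These two helpers are the single place the +1/-1 conversion happens.
to1based <- function(pos0) pos0 + 1L
to0based <- function(pos1) pos1 - 1L

#' Reverse complement of a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors (with names) as the working currency of the pipeline.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements, names preserved.
#' @export
#' @examples
#' revComp(c(a = "ACGTN"))
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Deterministic child seed derived from a parent seed and a stage offset,
# kept inside the 32-bit signed integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(offset)) %% 2147483629)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Random DNA of given length (uses the current RNG stream).
randomDna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent ordering (byte-wise, C locale) so id tie-breaks do not
# depend on the session's collation.
cOrder <- function(...) order(..., method = "radix")

cSort <- function(x) x[cOrder(x)]
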