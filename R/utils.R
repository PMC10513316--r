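# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' takes and returns plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CAATTCTTACCATCCACAAA")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half away from zero, the convention used for reported percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# validate a DNA sequence; names the first offending position on failure
assert_bases <- function(bases, min_len = 1L, what = "sequence") {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  if (nchar(bases) < min_len) {
    stop(sprintf("%s must have length >= %d (got %d)", what, min_len,
                 nchar(bases)), call. = FALSE)
  }
  invisible(bases)
}

# last / first n characters of a string
str_tail <- function(x, n) substr(x, nchar(x) - n + 1L, nchar(x))
str_head <- function(x, n) substr(x, 1L, n)

`%||%` <- function(a, b) if (is.null(a)) b else a
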