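#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector; characters outside `A/C/G/T` become
#' `N`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) abort("hamming(): unequal lengths")
  sum(av != bv)
}

# Uppercase and replace ambiguity codes by N.
normalise_bases <- function(x) {
  x <- toupper(x)
  stringr::str_replace_all(x, "[^ACGT]", "N")
}

check_scalar_fraction <- function(x, name, lo = 0, hi = 1,
                                  lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be a fraction in %s%s, %s%s",
                         name, if (lo_open) "(" else "[", format(lo),
                         format(hi), if (hi_open) ")" else "]"))
  invisible(x)
}
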