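#' Per-sequence G+C content
#'
#' `(G + C) / (A + C + G + T)`; N and other ambiguity codes are excluded
#' from both numerator and denominator. Sequences consisting only of N
#' return `NA`.
#'
#' @param bases Character vector of sequences, or a sequence-record tibble.
#' @return Numeric vector of G+C fractions.
#' @examples
#' gc_content(c("ACGT", "GGCC", "ANGT"))
#' @export
gc_content <- function(bases) {
  if (is.data.frame(bases)) bases <- bases$bases
  x <- Biostrings::DNAStringSet(bases)
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
}

#' G+C histogram of a read set
#'
#' @param reads Sequence-record tibble.
#' @param bin_width Histogram bin width on the GC fraction axis (default
#'   0.01).
#' @return A `gc_distribution` list: `histogram` (tibble `bin_center`,
#'   `count`), `mode` (GC at the peak bin; ties resolve to the lowest GC),
#'   `dispersion` (sample sd of per-read GC), `mean_read_length`, `n_reads`.
#' @export
gc_histogram <- function(reads, bin_width = 0.01) {
  if (nrow(reads) == 0) abort("at least one read is required")
  gc <- gc_content(reads$bases)
  gc <- gc[!is.na(gc)]
  edges <- seq(0, 1 + bin_width, by = bin_width)
  bin <- pmin(findInterval(gc, edges), length(edges) - 1)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  centers <- edges[-length(edges)] + bin_width / 2
  mode_bin <- which.max(counts) # which.max takes the first (lowest GC) tie
  structure(list(
    histogram = tibble(bin_center = centers, count = counts),
    mode = centers[mode_bin],
    dispersion = if (length(gc) > 1) sd(gc) else 0,
    mean_read_length = mean(nchar(reads$bases)),
    n_reads = nrow(reads)
  ), class = "gc_distribution")
}

#' Derive the stringent high-GC filter threshold from single-cell reads
#'
#' The threshold is the pooled single-cell GC mode plus `sigma_factor`
#' binomial standard deviations `sqrt(mode * (1 - mode) / mean_read_length)`,
#' rounded up to the nearest 0.01. With the default factor of 5.8 a mode of
#' 32.4% at 400 bp reads yields 0.46.
#'
#' @param single_cell_reads A sequence-record tibble, or list of them (one
#'   per cell); reads are pooled.
#' @param sigma_factor Width of the retention band in read-GC standard
#'   deviations (default 5.8).
#' @param bin_width Histogram bin width used to locate the mode.
#' @return The GC threshold as a fraction.
#' @export
derive_gc_threshold <- function(single_cell_reads, sigma_factor = 5.8,
                                bin_width = 0.01) {
  if (is.data.frame(single_cell_reads)) {
    single_cell_reads <- list(single_cell_reads)
  }
  if (length(single_cell_reads) == 0) abort("at least one read set required")
  pooled <- bind_rows(single_cell_reads)
  h <- gc_histogram(pooled, bin_width = bin_width)
  if (h$dispersion == 0) {
    # degenerate width: keep the mode itself, cut one bin above it
    return(ceiling(h$mode / bin_width - 1e-9) * bin_width + bin_width)
  }
  gc_threshold_from_mode(h$mode, h$mean_read_length,
                         sigma_factor = sigma_factor, bin_width = bin_width)
}

#' @rdname derive_gc_threshold
#' @param mode GC fraction at the single-cell distribution peak.
#' @param mean_read_length Mean read length in bases.
#' @export
gc_threshold_from_mode <- function(mode, mean_read_length,
                                   sigma_factor = 5.8, bin_width = 0.01) {
  width <- sigma_factor * sqrt(mode * (1 - mode) / mean_read_length)
  ceiling((mode + width) / bin_width - 1e-9) * bin_width
}

#' Filter parameters for the high-GC read filter
#'
#' @param gc_threshold Reads with GC strictly above this are removed
#'   (default 0.46).
#' @param rescue_criteria [map_criteria()] used by [rescue_high_gc()].
#' @return A `filter_params` list.
#' @export
filter_params <- function(gc_threshold = 0.46,
                          rescue_criteria = map_criteria()) {
  check_scalar_fraction(gc_threshold, "gc_threshold", lo = 0, hi = 1,
                        lo_open = TRUE, hi_open = TRUE)
  structure(list(gc_threshold = gc_threshold,
                 rescue_criteria = rescue_criteria),
            class = "filter_params")
}

#' Remove high-GC reads
#'
#' A read is removed iff its GC content strictly exceeds the threshold
#' (reads exactly at the boundary are retained); the result is an
#' exhaustive partition of the input.
#'
#' @param reads Sequence-record tibble.
#' @param params A [filter_params()].
#' @return List with `retained` and `removed` tibbles, each carrying a `gc`
#'   column.
#' @export
gc_filter <- function(reads, params = filter_params()) {
  gc <- gc_content(reads$bases)
  reads$gc <- gc
  removed <- !is.na(gc) & gc > params$gc_threshold
  list(retained = reads[!removed, , drop = FALSE],
       removed = reads[removed, , drop = FALSE])
}

#' Rescue high-GC reads by mapping to reference genomes
#'
#' Removed high-GC reads that map to a reference (by default at 90%
#' identity over 40 bases) are recovered, so that high-GC conserved regions
#' of the target (e.g. rRNA operons) are not lost to the composition
#' filter.
#'
#' @param removed Tibble of removed reads from [gc_filter()].
#' @param references Reference sequence-record tibble.
#' @param criteria A [map_criteria()].
#' @param scoring An [align_scoring()].
#' @return Tibble of rescued reads (subset of `removed`).
#' @export
rescue_high_gc <- function(removed, references, criteria = map_criteria(),
                           scoring = align_scoring()) {
  references <- as_records(references)
  if (nrow(references) == 0) abort("references must be non-empty")
  if (nrow(removed) == 0) return(removed)
  mp <- map_reads(removed, references, criteria = criteria,
                  scoring = scoring)
  removed[removed$id %in% mp$mapped$query_id, , drop = FALSE]
}

#' Write a GC histogram as two-column TSV
#'
#' @param dist A `gc_distribution` from [gc_histogram()].
#' @param path Output file.
#' @export
write_gc_histogram <- function(dist, path) {
  utils::write.table(dist$histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("bin_center", "count"))
  invisible(path)
}
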