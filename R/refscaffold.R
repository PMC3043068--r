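#' Orient assembly elements against a reference genome
#'
#' For each element, the scores of hits supporting the forward orientation
#' (element forward vs reference forward) and the reverse orientation are
#' summed separately; the orientation with the larger total wins.
#' Elements with no hits, or an exact tie, default to `+` and are flagged.
#'
#' @param elements Sequence-record tibble of contigs/scaffold sequences.
#' @param reference One-row sequence-record tibble (or string).
#' @param scoring An [align_scoring()].
#' @return Tibble: `element_id`, `orientation`, `score_fwd`, `score_rev`,
#'   `tie_or_no_hits`, plus the hit table as attribute `"hits"`.
#' @export
orient_elements <- function(elements, reference, scoring = align_scoring()) {
  reference <- as_records(reference)
  hits <- local_align(elements, reference, scoring = scoring)
  sums <- hits %>%
    group_by(.data$query_id, .data$strand) %>%
    summarise(score = sum(.data$score), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "strand", values_from = "score",
                       values_fill = 0)
  if (!"+" %in% names(sums)) sums[["+"]] <- 0
  if (!"-" %in% names(sums)) sums[["-"]] <- 0
  out <- tibble(element_id = elements$id) %>%
    left_join(rename(sums, element_id = "query_id"), by = "element_id") %>%
    mutate(score_fwd = dplyr::coalesce(.data[["+"]], 0),
           score_rev = dplyr::coalesce(.data[["-"]], 0),
           orientation = ifelse(.data$score_rev > .data$score_fwd, "-", "+"),
           tie_or_no_hits = .data$score_fwd == .data$score_rev) %>%
    select("element_id", "orientation", "score_fwd", "score_rev",
           "tie_or_no_hits")
  if (any(out$tie_or_no_hits)) {
    warn(sprintf("%d element(s) had no hits or tied scores; defaulting to '+'",
                 sum(out$tie_or_no_hits)))
  }
  attr(out, "hits") <- hits
  out
}

#' Order oriented elements along a reference
#'
#' Using only hits whose strand matches each element's chosen orientation,
#' the order key is the hit-length-weighted mean of the hit subject
#' midpoints; elements are sorted by ascending key. Elements with no
#' co-oriented hits are unplaced and appended after the placed ones in
#' input order.
#'
#' @param orientations Tibble from [orient_elements()] (its `"hits"`
#'   attribute is reused; otherwise supply `elements` and a reference via
#'   `hits`).
#' @param hits Optional hit tibble from [local_align()] (element vs
#'   reference) if `orientations` does not carry one.
#' @return Tibble: `element_id`, `orientation`, `order_key`, `placed`,
#'   sorted in layout order.
#' @export
order_elements <- function(orientations, hits = NULL) {
  hits <- hits %||% attr(orientations, "hits")
  if (is.null(hits)) abort("no hits available; pass `hits`")
  keyed <- hits %>%
    left_join(select(orientations, "element_id", "orientation"),
              by = c(query_id = "element_id")) %>%
    filter(.data$strand == .data$orientation) %>%
    group_by(.data$query_id) %>%
    summarise(order_key = sum(as.numeric(.data$length) *
                                (.data$s_start + .data$s_end) / 2) /
                sum(as.numeric(.data$length)), .groups = "drop")
  out <- orientations %>%
    left_join(rename(keyed, element_id = "query_id"), by = "element_id") %>%
    mutate(placed = !is.na(.data$order_key)) %>%
    select("element_id", "orientation", "order_key", "placed")
  bind_rows(arrange(filter(out, .data$placed), .data$order_key),
            filter(out, !.data$placed))
}

#' Reference-guided layout of an assembly
#'
#' Convenience wrapper: orient, then order, all elements against a
#' reference.
#'
#' @inheritParams orient_elements
#' @return The ordered layout tibble from [order_elements()].
#' @export
layout_elements <- function(elements, reference, scoring = align_scoring()) {
  ors <- suppressWarnings(orient_elements(elements, reference,
                                          scoring = scoring))
  order_elements(ors)
}

#' Apply a layout: ordered, orientation-corrected element sequences
#'
#' @param elements Sequence-record tibble.
#' @param layout Tibble from [order_elements()].
#' @return Sequence-record tibble in layout order with `-` elements
#'   reverse-complemented.
#' @export
apply_layout <- function(elements, layout) {
  idx <- match(layout$element_id, elements$id)
  bases <- elements$bases[idx]
  flip <- layout$orientation == "-"
  bases[flip] <- revcomp(bases[flip])
  seq_tbl(layout$element_id, bases)
}

#' Screen contigs against known contaminant references
#'
#' A contig is excluded when at least `min_cover` of its length is covered
#' by hits (meeting the mapping criteria) to any single contaminant
#' reference, as expected for sequences carried in by the MDA reagents.
#'
#' @param contigs Contig or sequence-record tibble.
#' @param contaminant_references Sequence-record tibble of contaminant
#'   genomes.
#' @param criteria A [map_criteria()].
#' @param min_cover Covered-fraction threshold for exclusion (default 0.5).
#' @param scoring An [align_scoring()].
#' @return List with `kept`, `excluded` (tibbles) and `report` (tibble:
#'   `contig_id`, `reference`, `covered_fraction` for each exclusion).
#' @export
contaminant_screen <- function(contigs, contaminant_references,
                               criteria = map_criteria(), min_cover = 0.5,
                               scoring = align_scoring()) {
  if (is.null(contaminant_references) ||
      (is.data.frame(contaminant_references) &&
       nrow(contaminant_references) == 0) ||
      length(contaminant_references) == 0) {
    return(list(kept = contigs, excluded = contigs[0, , drop = FALSE],
                report = tibble(contig_id = character(),
                                reference = character(),
                                covered_fraction = numeric())))
  }
  refs <- as_records(contaminant_references)
  hits <- local_align(contigs, refs, scoring = scoring, mode = "seeded")
  ok <- accept_hits(hits, criteria)
  cover <- ok %>%
    group_by(.data$query_id, .data$subject_id) %>%
    summarise(covered = sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = .data$q_start + 1L, end = .data$q_end)))),
      .groups = "drop")
  clen <- setNames(nchar(contigs$bases), contigs$id)
  cover$covered_fraction <- cover$covered / clen[cover$query_id]
  worst <- cover %>%
    group_by(.data$query_id) %>%
    slice_max(.data$covered_fraction, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    filter(.data$covered_fraction >= min_cover)
  excluded_ids <- worst$query_id
  list(
    kept = contigs[!contigs$id %in% excluded_ids, , drop = FALSE],
    excluded = contigs[contigs$id %in% excluded_ids, , drop = FALSE],
    report = tibble(contig_id = worst$query_id,
                    reference = worst$subject_id,
                    covered_fraction = worst$covered_fraction)
  )
}

#' Write a layout as TSV
#'
#' Columns: element, orientation, order_key, placed.
#'
#' @param layout Tibble from [order_elements()].
#' @param path Output file.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
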