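#' Alignment scoring and mapping acceptance parameters
#'
#' Defaults are megablast-like (+2/-3, gap open 5, extend 2), the
#' high-identity regime in which reads are accepted at 90% identity over 40
#' bases.
#'
#' @param match,mismatch Match reward and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @param k Seed k-mer size for the heuristic path (default 11).
#' @param min_score Score floor below which hits are not reported.
#' @param x_drop X-drop threshold for seed extension.
#' @param max_occ Seeds occurring more often than this in the subject are
#'   skipped (repeat masking).
#' @param exact_cells When `query length * subject length` is at most this,
#'   full affine-gap Smith-Waterman is used instead of seeded extension.
#' @return An `align_scoring` list.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L, k = 11L, min_score = 50L,
                          x_drop = 100L, max_occ = 400L,
                          exact_cells = 250000) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), k = as.integer(k),
                 min_score = as.integer(min_score),
                 x_drop = as.integer(x_drop), max_occ = as.integer(max_occ),
                 exact_cells = exact_cells),
            class = "align_scoring")
}

#' @rdname align_scoring
#' @param min_identity Minimum hit identity for acceptance (default 0.90).
#' @param min_length Minimum hit length in alignment columns (default 40).
#' @export
map_criteria <- function(min_identity = 0.90, min_length = 40L) {
  check_scalar_fraction(min_identity, "min_identity", lo = 0, hi = 1,
                        lo_open = TRUE)
  structure(list(min_identity = min_identity,
                 min_length = as.integer(min_length)),
            class = "map_criteria")
}

#' Local pairwise alignment
#'
#' Aligns every query against every subject on both strands. Small problems
#' are solved by full affine-gap Smith-Waterman (single best local hit);
#' large ones by exact k-mer seeding with ungapped X-drop extension (all
#' locally maximal hits above the score floor). Identity is matches divided
#' by alignment columns. Coordinates are 0-based, half-open, on the forward
#' strand of both sequences; `strand` is the query strand relative to the
#' subject.
#'
#' @param queries,subjects Sequence-record tibbles (or character vectors).
#' @param scoring An [align_scoring()].
#' @param mode `"auto"` (size-based choice), `"exact"`, or `"seeded"`.
#' @return A tibble of hits: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `identity`, `length`, `score`.
#' @examples
#' a <- seq_tbl("q", "ACGTACGTACGTACGTACGTACGTACGT")
#' local_align(a, a)
#' @export
local_align <- function(queries, subjects, scoring = align_scoring(),
                        mode = c("auto", "exact", "seeded")) {
  mode <- match.arg(mode)
  q <- as_records(queries)
  s <- as_records(subjects)
  if (nrow(q) == 0 || nrow(s) == 0) return(empty_hits())
  if (any(!nzchar(q$bases)) || any(!nzchar(s$bases))) {
    abort("sequences must be non-empty")
  }
  df <- cpp_local_align(q$bases, s$bases,
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, scoring$k, scoring$min_score,
                        scoring$x_drop, scoring$max_occ, scoring$exact_cells,
                        switch(mode, auto = 0L, exact = 1L, seeded = 2L))
  tibble(
    query_id = q$id[df$query], subject_id = s$id[df$subject],
    q_start = df$q_start, q_end = df$q_end,
    s_start = df$s_start, s_end = df$s_end,
    strand = df$strand,
    identity = ifelse(df$length > 0, df$matches / df$length, 0),
    length = df$length, score = df$score
  )
}

as_records <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(seq_tbl(ids, x))
  }
  x
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(), strand = character(),
         identity = numeric(), length = integer(), score = integer())
}

accept_hits <- function(hits, criteria) {
  filter(hits, .data$identity >= criteria$min_identity,
         .data$length >= criteria$min_length)
}

#' Map reads to a reference
#'
#' A read maps when some local hit reaches `min_identity` over at least
#' `min_length` alignment columns. The best hit per read is the one with
#' the highest score; ties are broken by lower subject id, then lower
#' subject start, so runs are reproducible.
#'
#' @param reads Sequence-record tibble.
#' @param reference Sequence-record tibble of reference sequences.
#' @param criteria A [map_criteria()] (default 90% identity over 40 bases).
#' @param scoring An [align_scoring()].
#' @return List with `mapped` (tibble of best hits, one row per mapped
#'   read) and `unmapped` (character vector of read ids).
#' @export
map_reads <- function(reads, reference, criteria = map_criteria(),
                      scoring = align_scoring()) {
  reference <- as_records(reference)
  if (nrow(reference) == 0) abort("reference must be non-empty")
  hits <- local_align(reads, reference, scoring = scoring)
  ok <- accept_hits(hits, criteria)
  best <- ok %>%
    arrange(.data$query_id, desc(.data$score), .data$subject_id,
            .data$s_start) %>%
    group_by(.data$query_id) %>%
    slice(1) %>%
    ungroup()
  list(mapped = best,
       unmapped = setdiff(reads$id, best$query_id))
}

#' Flag MDA chimeras by split alignment
#'
#' A read is called chimeric when no single hit covers at least
#' `min_single_cover` of it, while two disjoint query segments (each
#' meeting the mapping criteria) align to subject loci more than
#' `min_separation` bases apart or with inconsistent strands.
#'
#' @param reads Sequence-record tibble.
#' @param reference Reference sequences.
#' @param criteria A [map_criteria()].
#' @param min_single_cover Fraction of the read a single hit must cover to
#'   rule out chimerism (default 0.80). Note the geometric consequence:
#'   with a junction uniform within the read, only junctions between 20%
#'   and 80% of the read length are callable under this rule.
#' @param min_separation Minimum subject separation of the two segments
#'   (default 2000 bases).
#' @param max_segment_overlap Bases of query overlap tolerated between the
#'   two evidence segments (default 20; seed extension can overshoot a
#'   junction by a few bases).
#' @param scoring An [align_scoring()].
#' @return Tibble with `read_id`, `is_chimeric`, and evidence columns for
#'   the two segments (NA when not chimeric).
#' @export
flag_chimeras <- function(reads, reference, criteria = map_criteria(),
                          min_single_cover = 0.80, min_separation = 2000L,
                          max_segment_overlap = 20L,
                          scoring = align_scoring()) {
  reference <- as_records(reference)
  if (nrow(reference) == 0) abort("reference must be non-empty")
  hits <- local_align(reads, reference, scoring = scoring, mode = "seeded")
  ok <- accept_hits(hits, criteria)
  n <- nrow(reads)
  out <- tibble(
    read_id = reads$id, is_chimeric = FALSE,
    q_start1 = NA_integer_, q_end1 = NA_integer_,
    subject1 = NA_character_, s_start1 = NA_integer_,
    strand1 = NA_character_,
    q_start2 = NA_integer_, q_end2 = NA_integer_,
    subject2 = NA_character_, s_start2 = NA_integer_,
    strand2 = NA_character_)
  if (nrow(ok) == 0) return(out)
  rlen <- setNames(nchar(reads$bases), reads$id)
  # fast pre-screen: only reads with hits but no single covering hit can
  # be chimeric
  span <- ok %>%
    group_by(.data$query_id) %>%
    summarise(best_cover = max(.data$q_end - .data$q_start),
              .groups = "drop")
  cand <- span$query_id[span$best_cover <
                          min_single_cover * rlen[span$query_id]]
  if (length(cand) == 0) return(out)
  okl <- as.list(ok)   # column access by index, no tibble row slicing
  by_read <- split(seq_len(nrow(ok)), ok$query_id)
  for (rid in cand) {
    idx <- by_read[[rid]]
    idx <- idx[order(-okl$score[idx])]
    m <- length(idx)
    if (m < 2) next
    found <- FALSE
    for (i in seq_len(m - 1)) {
      if (found) break
      for (j in seq(i + 1, m)) {
        a <- idx[i]; b <- idx[j]
        qov <- min(okl$q_end[a], okl$q_end[b]) -
          max(okl$q_start[a], okl$q_start[b])
        if (qov > max_segment_overlap) next
        apart <- okl$subject_id[a] != okl$subject_id[b] ||
          abs((okl$s_start[a] + okl$s_end[a]) / 2 -
                (okl$s_start[b] + okl$s_end[b]) / 2) > min_separation ||
          okl$strand[a] != okl$strand[b]
        if (!apart) next
        r <- match(rid, out$read_id)
        out$is_chimeric[r] <- TRUE
        out$q_start1[r] <- okl$q_start[a]; out$q_end1[r] <- okl$q_end[a]
        out$subject1[r] <- okl$subject_id[a]
        out$s_start1[r] <- okl$s_start[a]; out$strand1[r] <- okl$strand[a]
        out$q_start2[r] <- okl$q_start[b]; out$q_end2[r] <- okl$q_end[b]
        out$subject2[r] <- okl$subject_id[b]
        out$s_start2[r] <- okl$s_start[b]; out$strand2[r] <- okl$strand[b]
        found <- TRUE
        break
      }
    }
  }
  out
}

#' Export alignment hits in BLAST outfmt-6 column order
#'
#' Tab-separated columns qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore; coordinates are converted to
#' 1-based inclusive and the evalue column is `NA` (no E-value model).
#'
#' @param hits Hit tibble from [local_align()].
#' @param path Output file.
#' @export
export_hits_tsv <- function(hits, path) {
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$identity * 100, 2), length = hits$length,
    mismatch = hits$length - round(hits$identity * hits$length),
    gapopen = 0L,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end),
    send = ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L),
    evalue = NA, bitscore = hits$score
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
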