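#' Reciprocal best hits between two gene sets
#'
#' Each gene's best hit (by alignment score; ties to the lower id) is
#' computed in both directions; a pair is reported when the two genes are
#' mutually best. Confidence is `"high"` when the forward hit covers at
#' least `coverage_threshold` of the query gene, `"low"` otherwise.
#' Protein sequences are aligned locally with a BLOSUM62 substitution
#' matrix; set `type = "nucleotide"` for nucleotide gene sets (which use
#' the package's nucleotide aligner).
#'
#' @param genes_a,genes_b Sequence-record tibbles (`bases` holds amino
#'   acids when `type = "protein"`).
#' @param coverage_threshold Forward query coverage for high confidence
#'   (default 0.60).
#' @param type `"protein"` or `"nucleotide"`.
#' @param scoring An [align_scoring()] (nucleotide type only).
#' @return Tibble: `gene_a`, `gene_b`, `identity_fwd`, `identity_rev`,
#'   `coverage_fwd`, `coverage_rev`, `confidence`.
#' @export
rbh <- function(genes_a, genes_b, coverage_threshold = 0.60,
                type = c("protein", "nucleotide"),
                scoring = align_scoring()) {
  type <- match.arg(type)
  if (nrow(genes_a) == 0 || nrow(genes_b) == 0) {
    abort("gene sets must be non-empty")
  }
  hits <- if (type == "protein") {
    protein_align_all(genes_a, genes_b)
  } else {
    local_align(genes_a, genes_b, scoring = scoring)
  }
  if (nrow(hits) == 0) return(rbh_empty())
  best_fwd <- hits %>%
    arrange(.data$query_id, desc(.data$score), .data$subject_id) %>%
    group_by(.data$query_id) %>% slice(1) %>% ungroup()
  best_rev <- hits %>%
    arrange(.data$subject_id, desc(.data$score), .data$query_id) %>%
    group_by(.data$subject_id) %>% slice(1) %>% ungroup()
  la <- setNames(nchar(genes_a$bases), genes_a$id)
  lb <- setNames(nchar(genes_b$bases), genes_b$id)
  mutual <- best_fwd %>%
    dplyr::inner_join(
      best_rev %>% select(rev_query = "query_id", "subject_id",
                          rev_identity = "identity", rev_len = "length",
                          rev_ss = "s_start", rev_se = "s_end"),
      by = "subject_id") %>%
    filter(.data$query_id == .data$rev_query)
  if (nrow(mutual) == 0) return(rbh_empty())
  tibble(
    gene_a = mutual$query_id, gene_b = mutual$subject_id,
    identity_fwd = mutual$identity, identity_rev = mutual$rev_identity,
    coverage_fwd = unname((mutual$q_end - mutual$q_start) /
                            la[mutual$query_id]),
    coverage_rev = unname((mutual$rev_se - mutual$rev_ss) /
                            lb[mutual$subject_id]),
    confidence = unname(ifelse((mutual$q_end - mutual$q_start) /
                                 la[mutual$query_id] >= coverage_threshold,
                               "high", "low"))
  ) %>% arrange(.data$gene_a)
}

rbh_empty <- function() {
  tibble(gene_a = character(), gene_b = character(),
         identity_fwd = numeric(), identity_rev = numeric(),
         coverage_fwd = numeric(), coverage_rev = numeric(),
         confidence = character())
}

# all-vs-all local protein alignment via Biostrings (BLOSUM62, affine gaps)
protein_align_all <- function(genes_a, genes_b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  subj <- Biostrings::AAStringSet(genes_b$bases)
  names(subj) <- genes_b$id
  rows <- purrr::imap(genes_a$bases, function(qseq, i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(rep(qseq, length(subj))),
      subject = subj, type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    tibble(
      query_id = genes_a$id[i], subject_id = names(subj),
      q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
      q_end = Biostrings::end(Biostrings::pattern(pa)),
      s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
      s_end = Biostrings::end(Biostrings::subject(pa)),
      strand = "+",
      identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
      length = Biostrings::nchar(pa),
      score = Biostrings::score(pa))
  })
  bind_rows(rows) %>% filter(.data$score > 0)
}

#' Average nucleotide identity over corresponding regions
#'
#' Corresponding regions are the reference positions covered by accepted
#' local hits between the two genomes; the identity is the
#' hit-length-weighted mean identity. Measured in the reference genome's
#' coordinate space.
#'
#' @param target,reference Sequence-record tibbles (target may have many
#'   contigs; reference is treated as one genome, possibly multi-element).
#' @param criteria A [map_criteria()] for accepting hits (defaults 90%/40;
#'   pass a looser one for diverged genome pairs).
#' @param floor_identity Identity assigned to non-corresponding regions by
#'   [whole_genome_identity()] (default 0.25).
#' @param scoring An [align_scoring()].
#' @return An `ani_report` one-row tibble: `corresponding_bases`,
#'   `identity_corresponding`, `reference_length`, `floor_identity`,
#'   `whole_genome_identity`.
#' @export
ani_corresponding <- function(target, reference,
                              criteria = map_criteria(min_identity = 0.5),
                              floor_identity = 0.25,
                              scoring = align_scoring()) {
  target <- as_records(target); reference <- as_records(reference)
  if (nrow(target) == 0 || nrow(reference) == 0) {
    abort("both genomes must be non-empty")
  }
  hits <- local_align(target, reference, scoring = scoring, mode = "seeded")
  ok <- accept_hits(hits, criteria)
  ref_len <- sum(nchar(reference$bases))
  if (nrow(ok) == 0) {
    return(ani_report(0L, 0, ref_len, floor_identity))
  }
  corr <- ok %>%
    group_by(.data$subject_id) %>%
    summarise(w = sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = .data$s_start + 1L, end = .data$s_end)))),
      .groups = "drop")
  corresponding <- sum(corr$w)
  ident <- sum(ok$identity * ok$length) / sum(ok$length)
  ani_report(corresponding, ident, ref_len, floor_identity)
}

#' @rdname ani_corresponding
#' @param corresponding_bases Bases in corresponding (aligned) regions on
#'   the reference.
#' @param identity_corresponding Length-weighted mean identity of the
#'   corresponding regions, in \[0, 1\].
#' @param reference_length Reference genome length in bases.
#' @export
ani_report <- function(corresponding_bases, identity_corresponding,
                       reference_length, floor_identity = 0.25) {
  if (corresponding_bases > reference_length) {
    abort("corresponding_bases must be <= reference_length")
  }
  out <- tibble(
    corresponding_bases = corresponding_bases,
    identity_corresponding = identity_corresponding,
    reference_length = reference_length,
    floor_identity = floor_identity
  )
  out$whole_genome_identity <- whole_genome_identity(out)
  class(out) <- c("ani_report", class(out))
  out
}

#' Whole-genome average identity with a floor for non-corresponding regions
#'
#' `(identity_corresponding * corresponding_bases + floor_identity *
#' (reference_length - corresponding_bases)) / reference_length`: aligned
#' regions contribute their measured identity and the unaligned remainder
#' of the reference is scored at the floor (default 25%).
#'
#' @param report An `ani_report` (or any tibble with the four fields).
#' @return Fraction in \[floor, 1\].
#' @export
whole_genome_identity <- function(report) {
  with(report, (identity_corresponding * corresponding_bases +
                  floor_identity * (reference_length - corresponding_bases)) /
         reference_length)
}

#' Per-position sequence novelty and alignment-depth tracks
#'
#' For each target position and each reference, the best-hit identity
#' covering that position is found (0 when uncovered); the novelty index
#' is `R - sum(identities)` for `R` references (2 with the default two
#' references), so 2 marks sequence with no homology to either reference.
#' The depth track counts hits covering each position.
#'
#' @param target One-row sequence-record tibble (e.g. an ordered genome).
#' @param references Sequence-record tibble of reference genomes (>= 1;
#'   the classic index uses 2).
#' @param criteria A [map_criteria()] for accepting hits.
#' @param scoring An [align_scoring()].
#' @param window Optional window size to average the per-position values
#'   into a track (default 1000; `NULL` returns per-position vectors).
#' @return List with `novelty` and `depth` track tibbles (or per-position
#'   numeric vectors when `window = NULL`).
#' @export
novelty_track <- function(target, references,
                          criteria = map_criteria(min_identity = 0.5),
                          scoring = align_scoring(), window = 1000L) {
  target <- as_records(target); references <- as_records(references)
  stopifnot(nrow(target) == 1, nrow(references) >= 1)
  L <- nchar(target$bases)
  nref <- nrow(references)
  ident_sum <- numeric(L)
  depth <- integer(L)
  for (r in seq_len(nref)) {
    hits <- local_align(target, references[r, , drop = FALSE],
                        scoring = scoring, mode = "seeded")
    ok <- accept_hits(hits, criteria)
    best <- numeric(L)
    if (nrow(ok) > 0) {
      for (i in seq_len(nrow(ok))) {
        a <- ok$q_start[i] + 1L; b <- ok$q_end[i]
        best[a:b] <- pmax(best[a:b], ok$identity[i])
        depth[a:b] <- depth[a:b] + 1L
      }
    }
    ident_sum <- ident_sum + best
  }
  novelty <- nref - ident_sum
  if (is.null(window)) {
    return(list(novelty = novelty, depth = depth))
  }
  starts <- seq(0L, L - window, by = window)
  idx <- function(v) vapply(starts, function(s) mean(v[(s + 1):(s + window)]),
                            numeric(1))
  list(
    novelty = tibble(element = target$id, start = starts,
                     end = starts + window, value = idx(novelty),
                     statistic = "novelty"),
    depth = tibble(element = target$id, start = starts,
                   end = starts + window, value = idx(depth),
                   statistic = "alignment_depth")
  )
}

#' Microheterogeneity across single-cell assemblies
#'
#' For each pair of assemblies, contigs of one are aligned to the other;
#' accepted hits define mutually corresponding regions whose
#' length-weighted identity and substitution count are reported (the
#' aligner's hits are gapless, so every non-matching column is a
#' substitution).
#'
#' @param assemblies Named list of [new_assembly()] objects (>= 2).
#' @param criteria A [map_criteria()].
#' @param scoring An [align_scoring()].
#' @return Tibble: `assembly_a`, `assembly_b`, `aligned_bases`, `ani`,
#'   `snps`, `snps_per_mb`.
#' @export
microheterogeneity <- function(assemblies,
                               criteria = map_criteria(),
                               scoring = align_scoring()) {
  stopifnot(length(assemblies) >= 2)
  nm <- names(assemblies) %||% paste0("assembly", seq_along(assemblies))
  out <- list()
  for (i in seq_len(length(assemblies) - 1)) {
    for (j in seq(i + 1, length(assemblies))) {
      hits <- local_align(assemblies[[i]]$contigs, assemblies[[j]]$contigs,
                          scoring = scoring, mode = "seeded")
      ok <- accept_hits(hits, criteria)
      if (nrow(ok) == 0) {
        out[[length(out) + 1]] <- tibble(
          assembly_a = nm[i], assembly_b = nm[j], aligned_bases = 0,
          ani = NA_real_, snps = 0, snps_per_mb = NA_real_)
        next
      }
      # keep each query region's best hit only (mutually-best corresponding
      # regions): non-overlapping greedy by score on the query side
      ok <- arrange(ok, desc(.data$score))
      kept <- logical(nrow(ok))
      used <- list()
      for (t in seq_len(nrow(ok))) {
        key <- ok$query_id[t]
        ivs <- used[[key]]
        a <- ok$q_start[t]; b <- ok$q_end[t]
        overlap <- FALSE
        if (!is.null(ivs)) {
          overlap <- any(pmax(a, ivs[, 1]) < pmin(b, ivs[, 2]))
        }
        if (!overlap) {
          kept[t] <- TRUE
          used[[key]] <- rbind(ivs, c(a, b))
        }
      }
      ok <- ok[kept, , drop = FALSE]
      aligned <- sum(ok$length)
      ani <- sum(ok$identity * ok$length) / aligned
      snps <- sum(round((1 - ok$identity) * ok$length))
      out[[length(out) + 1]] <- tibble(
        assembly_a = nm[i], assembly_b = nm[j], aligned_bases = aligned,
        ani = ani, snps = snps, snps_per_mb = snps / (aligned / 1e6))
    }
  }
  bind_rows(out)
}

#' Expected sequencing-error budget from quality scores
#'
#' A base with Phred quality Q is wrong with probability `10^(-Q/10)`. The
#' two-tier estimate takes `n_low` bases at an assumed low quality and
#' `n_high` at an assumed high quality; the exact estimate sums per-base
#' error probabilities over full quality strings when available. The MDA
#' polymerase contribution (`mda_error_rate * assembly_length`) is
#' reported separately.
#'
#' @param n_low_quality_bases,assumed_q_low Count and assumed Phred score
#'   of the low-quality tier (defaults 5904 bases at Q10).
#' @param n_high_quality_bases,assumed_q_high Count and assumed Phred
#'   score of the high-quality tier (default Q40).
#' @param quality_strings Optional character vector of Phred+33 strings
#'   for the exact estimate.
#' @param mda_error_rate Per-base MDA substitution rate (default 1e-5).
#' @param assembly_length Assembly length for the MDA contribution.
#' @return One-row tibble: `expected_errors_low_tier`,
#'   `expected_errors_high_tier`, `expected_errors_two_tier`,
#'   `expected_errors_exact` (NA without quality strings),
#'   `mda_expected_errors`.
#' @export
expected_errors <- function(n_low_quality_bases = 5904,
                            assumed_q_low = 10,
                            n_high_quality_bases = 0,
                            assumed_q_high = 40,
                            quality_strings = NULL,
                            mda_error_rate = 1e-5,
                            assembly_length = NULL) {
  stopifnot(n_low_quality_bases >= 0, n_high_quality_bases >= 0)
  low <- n_low_quality_bases * 10^(-assumed_q_low / 10)
  high <- n_high_quality_bases * 10^(-assumed_q_high / 10)
  exact <- if (!is.null(quality_strings)) {
    sum(vapply(quality_strings, function(q) {
      sum(10^(-(utf8ToInt(q) - 33) / 10))
    }, numeric(1)))
  } else NA_real_
  mda <- if (!is.null(assembly_length)) {
    mda_error_rate * assembly_length
  } else NA_real_
  tibble(
    expected_errors_low_tier = low,
    expected_errors_high_tier = high,
    expected_errors_two_tier = low + high,
    expected_errors_exact = exact,
    mda_expected_errors = mda
  )
}
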