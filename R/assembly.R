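#' Assembly container
#'
#' An assembly is a list of class `"assembly"` with
#' `contigs` (tibble: `id`, `bases`, `members` list-column of read ids),
#' `scaffolds` (tibble: `scaffold_id`, `part`, `contig_id`, `orientation`,
#' `gap_after` in bases, NA after the last part) and `unscaffolded`
#' (character vector of contig ids in no scaffold).
#'
#' @param contigs Contig tibble (or sequence-record tibble; a `members`
#'   column is added if absent).
#' @param scaffolds Scaffold membership tibble (default: none).
#' @return An `assembly` object.
#' @export
new_assembly <- function(contigs, scaffolds = NULL) {
  if (!"members" %in% names(contigs)) {
    contigs$members <- lapply(contigs$id, identity)
  }
  if (is.null(scaffolds)) {
    scaffolds <- tibble(scaffold_id = character(), part = integer(),
                        contig_id = character(), orientation = character(),
                        gap_after = numeric())
  }
  if (nrow(scaffolds) > 0 &&
      !all(scaffolds$contig_id %in% contigs$id)) {
    abort("every scaffold member must exist in contigs")
  }
  structure(list(
    contigs = contigs, scaffolds = scaffolds,
    unscaffolded = setdiff(contigs$id, scaffolds$contig_id)
  ), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf(
    "<assembly> %d contigs (%s bases), %d scaffolds, %d elements\n",
    nrow(x$contigs), format(st$contig_bases, big.mark = ","),
    st$n_scaffolds, st$n_elements))
  invisible(x)
}

#' Shredding parameters
#'
#' @param k Pseudo-read length (default 550).
#' @param overlap Bases shared by consecutive pseudo-reads (default 50).
#' @return A `shred_params` list.
#' @export
shred_params <- function(k = 550L, overlap = 50L) {
  if (!(overlap > 0 && overlap < k)) abort("need 0 < overlap < k")
  structure(list(k = as.integer(k), overlap = as.integer(overlap)),
            class = "shred_params")
}

#' Shred contigs into overlapping pseudo-reads
#'
#' Contigs are sampled as `k`-mers with `overlap`-base overlaps so that
#' contig-level evidence can enter a read-level assembly. Windows start at
#' multiples of `k - overlap`; a final window that would overrun is shifted
#' left to end exactly at the contig end, and contigs shorter than `k`
#' yield a single pseudo-read equal to the whole contig. Pseudo-read ids
#' encode the source contig and offset.
#'
#' @param contigs Contig or sequence-record tibble.
#' @param params A [shred_params()] (defaults: 550-mers, 50-base overlaps).
#' @return A sequence-record tibble of pseudo-reads.
#' @export
shred_contigs <- function(contigs, params = shred_params()) {
  k <- params$k; step <- params$k - params$overlap
  out <- purrr::pmap(list(contigs$id, contigs$bases), function(cid, seq) {
    L <- nchar(seq)
    if (L <= k) {
      starts <- 0L
    } else {
      n_win <- ceiling((L - k) / step) + 1
      starts <- pmin((seq_len(n_win) - 1L) * step, L - k)
    }
    tibble(id = sprintf("%s_shred_%07d", cid, starts),
           bases = substr(rep(seq, length(starts)), starts + 1, starts + k))
  })
  reads <- bind_rows(out)
  seq_tbl(reads$id, reads$bases)
}

#' Greedy overlap assembler
#'
#' Builds contigs by repeatedly merging the best-scoring suffix-prefix
#' overlap (both strands) meeting the thresholds, with a per-column vote
#' pileup giving a majority consensus. Reads are processed in a canonical
#' order (longest first, then id) and ties break toward the larger overlap
#' and then the lexicographically smaller read id, so the contig set is
#' invariant to input order. Contigs are reported in a canonical
#' orientation (lexicographically smaller of the two strands), longest
#' first.
#'
#' @param reads Sequence-record tibble.
#' @param min_overlap Minimum overlap length in bases (default 40).
#' @param min_overlap_identity Minimum identity across the overlap
#'   (default 0.97).
#' @return An [new_assembly()] with one singleton scaffold table (none).
#' @export
greedy_assemble <- function(reads, min_overlap = 40L,
                            min_overlap_identity = 0.97) {
  if (nrow(reads) == 0) abort("reads must be non-empty")
  res <- cpp_greedy_assemble(reads$bases, reads$id,
                             as.integer(min_overlap), min_overlap_identity,
                             2L, -3L, 16L, 4L)
  contigs <- tibble(
    id = sprintf("ctg_%05d", seq_along(res$bases)),
    bases = as.character(res$bases),
    members = res$members
  )
  new_assembly(contigs)
}

#' Scaffold contigs with paired-end links
#'
#' Two contigs are linked when at least `min_pairs` read pairs map to them
#' with a consistent relative orientation and an implied gap consistent
#' with the library span (within 3 standard deviations). Linked components
#' become scaffolds with the mean implied gap; conflicting links lose to
#' better-supported ones and cycles are broken at the weakest link.
#'
#' @param assembly An [new_assembly()].
#' @param pairs Sequence-record tibble with `mate` pairing set.
#' @param criteria A [map_criteria()] for read mapping.
#' @param span,sd_span Paired-end library outer span and its sd (defaults
#'   3000 +- 300).
#' @param min_pairs Minimum supporting pairs per link (default 3).
#' @param scoring An [align_scoring()].
#' @return A new `assembly` with scaffolds populated.
#' @export
scaffold_with_pairs <- function(assembly, pairs, criteria = map_criteria(),
                                span = 3000, sd_span = 300, min_pairs = 3L,
                                scoring = align_scoring()) {
  if (all(is.na(pairs$mate))) abort("`pairs` must carry pairing")
  mp <- map_reads(pairs, assembly$contigs, criteria = criteria,
                  scoring = scoring)$mapped
  hmap <- mp
  rownames_idx <- setNames(seq_len(nrow(hmap)), hmap$query_id)
  clen <- setNames(nchar(assembly$contigs$bases), assembly$contigs$id)

  # one row per pair with both mates mapped to different contigs
  p1 <- pairs$id[!is.na(pairs$mate) & pairs$id < pairs$mate]
  links <- purrr::map(p1, function(r1) {
    r2 <- pairs$mate[match(r1, pairs$id)]
    i1 <- rownames_idx[r1]; i2 <- rownames_idx[r2]
    if (is.na(i1) || is.na(i2)) return(NULL)
    h1 <- hmap[i1, ]; h2 <- hmap[i2, ]
    if (h1$subject_id == h2$subject_id) return(NULL)
    L1 <- clen[[h1$subject_id]]; L2 <- clen[[h2$subject_id]]
    o1 <- h1$strand
    d1 <- if (o1 == "+") L1 - h1$s_start else h1$s_end
    o2 <- if (h2$strand == "+") "-" else "+"
    d2 <- if (o2 == "+") h2$s_end else L2 - h2$s_start
    gap <- span - d1 - d2
    ca <- h1$subject_id; oa <- o1; cb <- h2$subject_id; ob <- o2
    if (ca > cb) {
      tmp <- ca; ca <- cb; cb <- tmp
      tmpo <- oa; oa <- flip_strand(ob); ob <- flip_strand(tmpo)
      # gap unchanged under reversal
    }
    tibble(ca = ca, oa = oa, cb = cb, ob = ob, gap = gap)
  })
  links <- bind_rows(links)
  if (nrow(links) == 0) return(assembly)
  grp <- links %>%
    group_by(.data$ca, .data$oa, .data$cb, .data$ob) %>%
    summarise(n = n(), gap = mean(.data$gap),
              spread = max(abs(.data$gap - stats::median(.data$gap))),
              .groups = "drop") %>%
    filter(.data$n >= min_pairs, .data$spread <= 3 * sd_span,
           abs(.data$gap) <= span) %>%
    arrange(desc(.data$n), .data$ca, .data$cb)
  if (nrow(grp) == 0) return(assembly)

  chains <- build_chains(grp, assembly$contigs$id)
  scaff <- chains_to_scaffolds(chains)
  new_assembly(assembly$contigs, scaff)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Greedy chain building over oriented contig links. Each link joins the
# right end of (ca, oa) to the left end of (cb, ob); the same physical join
# reads equivalently as right end of (cb, flip ob) to left end of (ca,
# flip oa). Links arrive sorted by support, so conflicting or
# cycle-forming links lose to better-supported ones (the weakest link of
# any would-be cycle is the one dropped).
build_chains <- function(grp, all_ids) {
  orient <- list()                       # contig -> assigned orientation
  comp <- setNames(seq_along(all_ids), all_ids)
  right_used <- character(0); left_used <- character(0)
  edges <- list()
  for (i in seq_len(nrow(grp))) {
    e <- grp[i, ]
    # resolve the link direction against already-assigned orientations
    forms <- list(
      list(ca = e$ca, oa = e$oa, cb = e$cb, ob = e$ob),
      list(ca = e$cb, oa = flip_strand(e$ob),
           cb = e$ca, ob = flip_strand(e$oa))
    )
    chosen <- NULL
    for (f in forms) {
      ok_a <- is.null(orient[[f$ca]]) || orient[[f$ca]] == f$oa
      ok_b <- is.null(orient[[f$cb]]) || orient[[f$cb]] == f$ob
      if (ok_a && ok_b) { chosen <- f; break }
    }
    if (is.null(chosen)) next                       # orientation conflict
    if (comp[[chosen$ca]] == comp[[chosen$cb]] &&
        !is.null(orient[[chosen$ca]]) && !is.null(orient[[chosen$cb]])) {
      next                                          # would close a cycle
    }
    key_r <- paste0(chosen$ca, ":R"); key_l <- paste0(chosen$cb, ":L")
    if (key_r %in% right_used || key_l %in% left_used) next
    right_used <- c(right_used, key_r); left_used <- c(left_used, key_l)
    orient[[chosen$ca]] <- chosen$oa; orient[[chosen$cb]] <- chosen$ob
    comp[comp == comp[[chosen$cb]]] <- comp[[chosen$ca]]
    edges[[length(edges) + 1]] <- tibble(ca = chosen$ca, cb = chosen$cb,
                                         gap = e$gap)
  }
  list(edges = bind_rows(edges), orient = orient)
}

chains_to_scaffolds <- function(chains) {
  edges <- chains$edges
  empty <- tibble(scaffold_id = character(), part = integer(),
                  contig_id = character(), orientation = character(),
                  gap_after = numeric())
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  starts <- sort(setdiff(edges$ca, edges$cb))
  out <- list(); sid <- 0
  for (s in starts) {
    sid <- sid + 1
    cur <- s; part <- 0; rows <- list()
    repeat {
      part <- part + 1
      ei <- match(cur, edges$ca)
      rows[[part]] <- tibble(
        scaffold_id = sprintf("scaffold_%03d", sid), part = part,
        contig_id = cur, orientation = chains$orient[[cur]] %||% "+",
        gap_after = if (!is.na(ei)) max(0, edges$gap[ei]) else NA_real_)
      if (is.na(ei) || part > nrow(edges) + 1) break
      cur <- edges$cb[ei]
    }
    out[[sid]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Assembly summary statistics
#'
#' N50 is the length of the smallest element in the minimal set of largest
#' elements whose summed length reaches half the total. Scaffold lengths
#' include estimated gaps; the element count is scaffolds plus unscaffolded
#' contigs.
#'
#' @param assembly An [new_assembly()].
#' @return A one-row tibble with `n_elements`, `n_scaffolds`,
#'   `scaffold_bases`, `contig_bases`, `scaffold_n50`, `contig_n50`,
#'   `largest_scaffold`, `largest_contig`, `unscaffolded_contigs`.
#' @export
assembly_stats <- function(assembly) {
  clen <- setNames(nchar(assembly$contigs$bases), assembly$contigs$id)
  sc <- assembly$scaffolds
  if (nrow(sc) > 0) {
    slen <- sc %>%
      group_by(.data$scaffold_id) %>%
      summarise(len = sum(clen[.data$contig_id]) +
                  sum(.data$gap_after, na.rm = TRUE), .groups = "drop") %>%
      pull(.data$len)
  } else slen <- numeric(0)
  # elements = scaffolds + unscaffolded contigs; their lengths
  elem_len <- c(slen, unname(clen[assembly$unscaffolded]))
  tibble(
    n_elements = length(elem_len),
    n_scaffolds = length(slen),
    scaffold_bases = sum(slen),
    contig_bases = sum(clen),
    scaffold_n50 = n50(slen),
    contig_n50 = n50(unname(clen)),
    largest_scaffold = if (length(slen)) max(slen) else 0,
    largest_contig = if (length(clen)) max(clen) else 0,
    unscaffolded_contigs = length(assembly$unscaffolded)
  )
}

#' N50 of a set of element lengths
#'
#' @param lengths Numeric vector of element lengths.
#' @return The N50 length (0 for empty input).
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Write an assembly as FASTA plus an AGP-like scaffold table
#'
#' @param assembly An [new_assembly()].
#' @param fasta_path,scaffold_path Output files.
#' @export
write_assembly <- function(assembly, fasta_path, scaffold_path = NULL) {
  write_fasta(assembly$contigs, fasta_path)
  if (!is.null(scaffold_path)) {
    utils::write.table(assembly$scaffolds, scaffold_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
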