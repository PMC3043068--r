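#' Windowed G+C content track
#'
#' Sliding windows at fixed step; the final partial window is dropped. N
#' bases are excluded from both numerator and denominator.
#'
#' @param genome One-row sequence-record tibble or a string.
#' @param window Window size in bases (default 5000).
#' @param step Step between window starts (default 1000).
#' @return A track tibble: `element`, `start`, `end` (0-based half-open),
#'   `value`, `statistic`.
#' @export
windowed_gc <- function(genome, window = 5000L, step = 1000L) {
  make_track(genome, window, step, "gc", function(w) {
    f <- Biostrings::letterFrequency(w, c("A", "C", "G", "T"))
    denom <- rowSums(f)
    ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
  })
}

make_track <- function(genome, window, step, statistic, fun) {
  genome <- as_records(genome)
  stopifnot(nrow(genome) == 1)
  L <- nchar(genome$bases)
  if (window > L) abort("`window` must not exceed the genome length")
  if (step > window) abort("`step` must be <= `window`")
  starts <- seq(0L, L - window, by = step)
  x <- Biostrings::DNAString(genome$bases)
  views <- Biostrings::Views(x, start = starts + 1L, width = window)
  tibble(element = genome$id, start = starts, end = starts + window,
         value = fun(views), statistic = statistic)
}

#' GC skew track
#'
#' Per window `(G - C) / (G + C)` (0 where G + C = 0). The cumulative
#' variant is the running sum of the per-window `G - C` counts, a curve
#' whose extrema mark strand-composition transition points.
#'
#' @inheritParams windowed_gc
#' @param cumulative Return the cumulative count-difference curve instead
#'   of the per-window ratio.
#' @return A track tibble (statistic `"gc_skew"` or `"gc_skew_cumulative"`).
#' @export
gc_skew <- function(genome, window = 5000L, step = 1000L,
                    cumulative = FALSE) {
  if (cumulative) {
    # non-overlapping windows so counts telescope over the genome
    tr <- make_track(genome, window = step, step = step,
                     statistic = "gc_skew_cumulative", function(w) {
      f <- Biostrings::letterFrequency(w, c("G", "C"))
      f[, "G"] - f[, "C"]
    })
    tr$value <- cumsum(tr$value)
    tr
  } else {
    make_track(genome, window, step, "gc_skew", function(w) {
      f <- Biostrings::letterFrequency(w, c("G", "C"))
      tot <- f[, "G"] + f[, "C"]
      ifelse(tot > 0, (f[, "G"] - f[, "C"]) / tot, 0)
    })
  }
}

#' Oligomer (e.g. GGGT) skew track
#'
#' Per window `(n(motif) - n(revcomp motif)) / (n(motif) + n(revcomp
#' motif))`, counting overlapping occurrences on the forward strand; 0
#' where both counts are 0. The cumulative variant is the running sum of
#' the count differences. The default motif GGGT against its reverse
#' complement ACCC is the oligomer-skew convention used for replication
#' origin detection in archaea.
#'
#' @inheritParams gc_skew
#' @param motif Motif string (must not equal its own reverse complement).
#' @return A track tibble.
#' @export
oligo_skew <- function(genome, motif = "GGGT", window = 5000L,
                       step = 1000L, cumulative = FALSE) {
  if (!nzchar(motif)) abort("`motif` must be non-empty")
  rc <- cpp_revcomp(toupper(motif))
  if (rc == toupper(motif)) {
    abort("motif equals its own reverse complement; skew undefined")
  }
  m1 <- Biostrings::DNAString(toupper(motif))
  m2 <- Biostrings::DNAString(rc)
  count_fun <- function(w) {
    n1 <- vapply(seq_along(w), function(i)
      Biostrings::countPattern(m1, w[[i]]), integer(1))
    n2 <- vapply(seq_along(w), function(i)
      Biostrings::countPattern(m2, w[[i]]), integer(1))
    cbind(n1, n2)
  }
  if (cumulative) {
    tr <- make_track(genome, window = step, step = step,
                     statistic = sprintf("%s_skew_cumulative", motif),
                     function(w) { cc <- count_fun(w); cc[, 1] - cc[, 2] })
    tr$value <- cumsum(tr$value)
    tr
  } else {
    make_track(genome, window, step, sprintf("%s_skew", motif),
               function(w) {
      cc <- count_fun(w)
      tot <- cc[, 1] + cc[, 2]
      ifelse(tot > 0, (cc[, 1] - cc[, 2]) / tot, 0)
    })
  }
}

#' Transition points of a cumulative skew track
#'
#' Local extrema of the cumulative curve, ranked by prominence (the
#' absolute offset from the line joining the track ends). A monotone track
#' has no internal transition and returns its endpoints flagged
#' accordingly.
#'
#' @param track Cumulative track tibble (>= 3 windows).
#' @return Tibble: `position` (window start), `value`, `kind`
#'   (`"minimum"`/`"maximum"`/`"endpoint"`), `prominence`, sorted by
#'   descending prominence; attribute `"no_internal_transition"` is TRUE
#'   for monotone tracks.
#' @export
find_transitions <- function(track) {
  v <- track$value
  n <- length(v)
  if (n < 3) abort("track needs at least 3 windows")
  # detrend against the chord joining the track ends: slope changes of the
  # cumulative curve become extrema of the detrended curve, so a
  # composition transition is the detrended extremum regardless of the
  # genome-wide net skew
  chord <- v[1] + (v[n] - v[1]) * (seq_len(n) - 1) / (n - 1)
  d <- v - chord
  sgn <- sign(diff(d))
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  turn <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0) + 1
  if (length(turn) == 0) {
    out <- tibble(position = track$start[c(1, n)], value = v[c(1, n)],
                  kind = "endpoint", prominence = 0)
    attr(out, "no_internal_transition") <- TRUE
    return(out)
  }
  out <- tibble(
    position = track$start[turn], value = v[turn],
    kind = ifelse(sgn[turn] > 0, "minimum", "maximum"),
    prominence = abs(d[turn])
  ) %>% arrange(desc(.data$prominence))
  attr(out, "no_internal_transition") <- FALSE
  out
}

ALL_CODONS <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(all64)
}

#' Codon usage table
#'
#' In-frame codon counts over a set of coding sequences, with frequencies
#' per thousand codons. Sequences whose length is not a multiple of 3 are
#' truncated to the last full codon (with a warning); codons containing N
#' are skipped.
#'
#' @param cds Sequence-record tibble (or character vector) of coding
#'   sequences.
#' @return A tibble with one row per codon (all 64): `codon`, `count`,
#'   `per_mille`.
#' @export
codon_usage <- function(cds) {
  cds <- as_records(cds)
  if (nrow(cds) == 0) abort("empty CDS set")
  bad <- nchar(cds$bases) %% 3 != 0
  if (any(bad)) {
    warn(sprintf("%d CDS length(s) not divisible by 3; truncating",
                 sum(bad)))
  }
  counts <- integer(length(ALL_CODONS))
  names(counts) <- ALL_CODONS
  for (s in cds$bases) {
    L <- nchar(s) - nchar(s) %% 3
    if (L < 3) next
    cod <- substring(s, seq(1, L, 3), seq(3, L, 3))
    tb <- table(cod[cod %in% ALL_CODONS])
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  total <- sum(counts)
  tibble(codon = ALL_CODONS, count = unname(counts),
         per_mille = if (total > 0) unname(counts) / total * 1000 else 0)
}

#' Nucleotide-matched scrambled control for codon usage
#'
#' Each CDS is independently shuffled at the nucleotide level (the exact
#' multiset of bases is preserved) and then read in frame, destroying
#' codon structure while keeping composition. Deterministic under `seed`.
#'
#' @param cds Sequence-record tibble or character vector.
#' @param seed Integer seed.
#' @return A sequence-record tibble of scrambled CDS.
#' @export
scrambled_control <- function(cds, seed = 1L) {
  cds <- as_records(cds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "scramble"))
  shuffled <- vapply(cds$bases, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  seq_tbl(paste0(cds$id, "_scrambled"), shuffled)
}

#' Distance between codon usage tables
#'
#' Euclidean distance between per-thousand frequency vectors by default;
#' cosine distance (1 - cosine similarity) available.
#'
#' @param a,b Codon usage tables from [codon_usage()].
#' @param method `"euclidean"` or `"cosine"`.
#' @return Nonnegative scalar distance.
#' @export
codon_usage_distance <- function(a, b, method = c("euclidean", "cosine")) {
  method <- match.arg(method)
  if (!identical(a$codon, b$codon)) abort("tables must share the codon set")
  x <- a$per_mille; y <- b$per_mille
  if (method == "euclidean") {
    sqrt(sum((x - y)^2))
  } else {
    1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
}

#' Gene table constructor
#'
#' @param id,element Gene id and assembly element.
#' @param start,end 0-based half-open coordinates on the element.
#' @param strand `+`/`-`.
#' @param category One of `CDS`, `pseudogene`, `tRNA`, `rRNA`,
#'   `other_RNA`.
#' @param annotation One of `functional`, `conserved_hypothetical`,
#'   `hypothetical` (optional).
#' @return A tibble of genes.
#' @export
gene_table <- function(id, element, start, end, strand = "+",
                       category = "CDS", annotation = NA_character_) {
  cats <- c("CDS", "pseudogene", "tRNA", "rRNA", "other_RNA")
  if (!all(category %in% cats)) {
    abort(sprintf("category must be one of %s", paste(cats, collapse = ", ")))
  }
  if (any(start >= end)) abort("gene start must be < end")
  tibble(id = as.character(id), element = as.character(element),
         start = as.integer(start), end = as.integer(end),
         strand = strand, category = category, annotation = annotation)
}

#' Annotation summary statistics
#'
#' Totals by category, ORF density per kb (2 decimals), coding fraction
#' (union of CDS + pseudogene intervals over the assembly length, nesting
#' and overlap handled), and average gene length.
#'
#' @param genes Gene tibble from [gene_table()].
#' @param assembly_length Total assembly length in bases.
#' @return One-row tibble: `total_genes`, `orfs`, `pseudogenes`,
#'   `rna_genes`, `coding_fraction`, `orf_density`, `mean_gene_length`.
#' @export
annotation_summary <- function(genes, assembly_length) {
  stopifnot(assembly_length > 0)
  if (any(genes$end > assembly_length)) {
    warn("some genes extend beyond `assembly_length`")
  }
  orfs <- sum(genes$category == "CDS")
  pseudo <- sum(genes$category == "pseudogene")
  rna <- sum(genes$category %in% c("tRNA", "rRNA", "other_RNA"))
  coding <- genes[genes$category %in% c("CDS", "pseudogene"), , drop = FALSE]
  coding_bases <- if (nrow(coding) > 0) {
    sum(by_element_union_width(coding))
  } else 0
  tibble(
    total_genes = orfs + pseudo + rna,
    orfs = orfs, pseudogenes = pseudo, rna_genes = rna,
    coding_fraction = coding_bases / assembly_length,
    orf_density = round(orfs / (assembly_length / 1000), 2),
    mean_gene_length = if (nrow(genes)) mean(genes$end - genes$start) else 0
  )
}

by_element_union_width <- function(genes) {
  vapply(split(genes, genes$element), function(g) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = g$start + 1L, end = g$end))))
  }, numeric(1))
}

#' Write a track as BedGraph
#'
#' Four columns: element, start, end, value (0-based half-open, the native
#' BedGraph convention).
#'
#' @param track Track tibble.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("element", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
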