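#' Genome specification for the synthetic community
#'
#' Describes an i.i.d.-composition genome with a target G+C fraction and an
#' optional composition switch: downstream of `composition_switch` the G:C
#' ratio on the forward strand becomes `gc_ratio_after` (default 60:40) at
#' unchanged total G+C, which plants a strand-composition transition that
#' skew statistics should detect.
#'
#' @param length Genome length in bases.
#' @param gc Target G+C fraction in (0, 1); boundaries 0 and 1 allowed for
#'   degenerate test genomes.
#' @param composition_switch Optional 0-based position where the strand
#'   composition flips; must be < `length`.
#' @param gc_ratio_after Fraction of the G+C mass assigned to G after the
#'   switch (before the switch G and C are balanced).
#' @param name Genome id.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length, gc, composition_switch = NULL,
                        gc_ratio_after = 0.6, name = "genome") {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(composition_switch) && composition_switch >= length) {
    abort("`composition_switch` must be < genome length")
  }
  structure(list(length = as.integer(length), gc = gc,
                 composition_switch = composition_switch,
                 gc_ratio_after = gc_ratio_after, name = name),
            class = "genome_spec")
}

#' Simulate a genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`; before the composition
#' switch G and C are balanced, after it the G share is `gc_ratio_after`.
#' Deterministic under `seed`.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A one-row sequence-record tibble.
#' @examples
#' g <- simulate_genome(genome_spec(1000, 0.324), seed = 1)
#' @export
simulate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "genome"))
  at <- (1 - spec$gc) / 2
  draw <- function(n, g_share) {
    if (n <= 0) return(character(0))
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(at, spec$gc * (1 - g_share), spec$gc * g_share, at))
  }
  sw <- spec$composition_switch
  if (is.null(sw)) {
    bases <- draw(spec$length, 0.5)
  } else {
    bases <- c(draw(sw, 0.5), draw(spec$length - sw, spec$gc_ratio_after))
  }
  seq_tbl(spec$name, paste(bases, collapse = ""))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Community specification: one low-GC target plus high-GC contaminants
#'
#' The default desk-scale community mirrors an archaeal enrichment dominated
#' by a low-GC target organism (~84% of cells) with high-GC bacterial
#' contaminants making up the remainder.
#'
#' @param target [genome_spec()] for the target organism.
#' @param contaminants List of [genome_spec()]s for contaminant genomes.
#' @param target_fraction Cell fraction of the target organism (default
#'   0.84).
#' @param contaminant_weights Relative abundances of the contaminants
#'   (default equal).
#' @return A `community_spec` list.
#' @export
community_spec <- function(target, contaminants = list(),
                           target_fraction = 0.84,
                           contaminant_weights = NULL) {
  check_scalar_fraction(target_fraction, "target_fraction",
                        lo = 0, hi = 1, lo_open = TRUE)
  if (is.null(contaminant_weights)) {
    contaminant_weights <- rep(1, length(contaminants))
  }
  if (length(contaminant_weights) != length(contaminants) ||
      any(contaminant_weights <= 0)) {
    abort("`contaminant_weights` must be positive, one per contaminant")
  }
  structure(list(target = target, contaminants = contaminants,
                 target_fraction = target_fraction,
                 contaminant_weights = contaminant_weights),
            class = "community_spec")
}

#' Default desk-scale community
#'
#' A 200 kb target genome at 32.4% G+C with a composition switch at its
#' midpoint, plus two 100 kb contaminants at 58% and 65% G+C; the target
#' makes up 84% of cells.
#'
#' @param target_length Target genome length (default 200 kb).
#' @return A `community_spec`.
#' @export
default_community <- function(target_length = 200000L) {
  community_spec(
    target = genome_spec(target_length, 0.324,
                         composition_switch = target_length %/% 2,
                         name = "target"),
    contaminants = list(
      genome_spec(100000L, 0.58, name = "contam_gc58"),
      genome_spec(100000L, 0.65, name = "contam_gc65")
    ),
    target_fraction = 0.84
  )
}

#' Materialise a community's genome sequences
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed.
#' @return List with `genomes` (sequence-record tibble, `source` marking
#'   target vs contaminant), `spec`, and `weights` (read-allocation weights
#'   proportional to cell fraction times genome length).
#' @export
build_community <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "community_spec"))
  specs <- c(list(spec$target), spec$contaminants)
  roles <- c("target", rep("contaminant", length(spec$contaminants)))
  gs <- purrr::imap(specs, function(s, i) {
    g <- simulate_genome(s, seed = derive_seed(seed, paste0("community", i)))
    g$source <- roles[i]
    g
  })
  genomes <- dplyr::bind_rows(gs)
  cellfrac <- c(spec$target_fraction,
                (1 - spec$target_fraction) *
                  spec$contaminant_weights / sum(spec$contaminant_weights))
  if (length(spec$contaminants) == 0) cellfrac <- spec$target_fraction
  weights <- tibble(
    genome = genomes$id, role = genomes$source,
    cell_fraction = cellfrac[seq_len(nrow(genomes))],
    length = nchar(genomes$bases)
  )
  list(genomes = genomes, spec = spec, weights = weights)
}

# Calibrated default: fraction of the log-gain distribution dropped so that
# one cell at 20x mean depth leaves about 60% of the genome recoverable
# (see simulate_bias_profile).
DEFAULT_DROPOUT_QUANTILE <- 0.10

#' Simulate a per-cell MDA amplification-bias profile
#'
#' The genome is tiled by segments with exponentially distributed lengths;
#' each segment receives a lognormal relative amplification gain, and
#' segments whose log-gain falls below the `dropout_quantile` quantile of
#' the gain distribution drop out entirely (gain 0). Distinct seeds give
#' independent profiles, emulating the cell-to-cell independence of MDA
#' bias.
#'
#' @param genome_length Genome length in bases.
#' @param mean_segment Mean segment length (default 10 kb).
#' @param sigma Standard deviation of the log-gains (default 2.5; 0 gives a
#'   uniform profile).
#' @param dropout_quantile Fraction of the gain distribution dropped
#'   (default calibrated so a cell at 20x depth has ~60% of the genome
#'   recoverable; set 0 to disable dropout, as for a bulk sample).
#' @param seed Integer seed.
#' @return A tibble with columns `start`, `end` (0-based half-open) and
#'   `gain`, carrying the seed as an attribute.
#' @export
simulate_bias_profile <- function(genome_length, mean_segment = 10000,
                                  sigma = 2.5,
                                  dropout_quantile = DEFAULT_DROPOUT_QUANTILE,
                                  seed = 1L) {
  stopifnot(genome_length > mean_segment)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "bias"))
  n_guess <- ceiling(genome_length / mean_segment * 3) + 5
  lens <- ceiling(rexp(n_guess, rate = 1 / mean_segment))
  while (sum(lens) < genome_length) {
    lens <- c(lens, ceiling(rexp(n_guess, rate = 1 / mean_segment)))
  }
  ends <- pmin(cumsum(lens), genome_length)
  keep <- which(c(TRUE, diff(ends) > 0))
  ends <- ends[keep]
  starts <- c(0, head(ends, -1))
  ns <- length(ends)
  loggain <- rnorm(ns, 0, sigma)
  gain <- exp(loggain)
  if (dropout_quantile > 0 && sigma > 0) {
    cut <- qnorm(dropout_quantile, 0, sigma)
    gain[loggain < cut] <- 0
  }
  if (all(gain == 0)) gain[which.max(loggain)] <- exp(max(loggain))
  out <- tibble(start = as.integer(starts), end = as.integer(ends),
                gain = gain)
  attr(out, "seed") <- seed
  attr(out, "genome_length") <- as.integer(genome_length)
  out
}

#' Uniform (bulk) bias profile
#'
#' A mildly biased profile without dropout, emulating bulk MDA of many
#' pooled cells.
#'
#' @inheritParams simulate_bias_profile
#' @export
bulk_bias_profile <- function(genome_length, mean_segment = 10000,
                              sigma = 0.8, seed = 1L) {
  simulate_bias_profile(genome_length, mean_segment = mean_segment,
                        sigma = sigma, dropout_quantile = 0, seed = seed)
}

#' Per-base expected coverage and recoverable fraction of a bias profile
#'
#' Expected depth of segment i at mean depth `depth` is
#' `depth * gain_i / wmean(gain)` (length-weighted mean over the genome). A
#' base is recoverable when its expected depth reaches `min_cov`, the
#' coverage needed for reads to overlap into contigs.
#'
#' @param profile Tibble from [simulate_bias_profile()].
#' @param depth Mean sequencing depth.
#' @param min_cov Minimum expected depth for assembly (default 1, which matches the realized assembled fraction of the greedy assembler at these read lengths).
#' @return `recoverable_fraction()`: a single fraction.
#'   `recoverable_segments()`: the profile with `exp_depth` and
#'   `recoverable` columns.
#' @export
recoverable_segments <- function(profile, depth = 20, min_cov = 1) {
  len <- profile$end - profile$start
  wmean <- sum(profile$gain * len) / sum(len)
  profile %>%
    mutate(exp_depth = depth * .data$gain / wmean,
           recoverable = .data$exp_depth >= min_cov)
}

#' @rdname recoverable_segments
#' @export
recoverable_fraction <- function(profile, depth = 20, min_cov = 1) {
  seg <- recoverable_segments(profile, depth, min_cov)
  sum((seg$end - seg$start)[seg$recoverable]) / sum(seg$end - seg$start)
}

#' Read model for 454-like shotgun and paired-end reads
#'
#' @param mean_len,sd_len Shotgun read length distribution (default 400 +-
#'   50, truncated to \[50, 800\]).
#' @param pair_span,sd_span Paired-end outer span (default 3000 +- 300).
#' @param base_quality Mean per-base Phred quality (default 30).
#' @param quality_sd Per-base quality jitter (default 3).
#' @param sub_error_rate_from_quality Apply substitution errors at the
#'   per-base rate implied by the simulated quality scores.
#' @param chimera_rate Fraction of shotgun reads that are MDA chimeras
#'   (default 0.01).
#' @param mda_sub_rate MDA polymerase substitution rate (default 1e-5).
#' @return A `read_model` list.
#' @export
read_model <- function(mean_len = 400, sd_len = 50,
                       pair_span = 3000, sd_span = 300,
                       base_quality = 30, quality_sd = 3,
                       sub_error_rate_from_quality = TRUE,
                       chimera_rate = 0.01, mda_sub_rate = 1e-5) {
  check_scalar_fraction(chimera_rate, "chimera_rate")
  check_scalar_fraction(mda_sub_rate, "mda_sub_rate")
  stopifnot(mean_len > 0, pair_span > 0)
  structure(list(mean_len = mean_len, sd_len = sd_len,
                 pair_span = pair_span, sd_span = sd_span,
                 base_quality = base_quality, quality_sd = quality_sd,
                 sub_error_rate_from_quality = sub_error_rate_from_quality,
                 chimera_rate = chimera_rate, mda_sub_rate = mda_sub_rate),
            class = "read_model")
}

# sample read lengths, truncated
sample_lengths <- function(n, model, lo = 50, hi = 800) {
  len <- round(rnorm(n, model$mean_len, model$sd_len))
  pmin(pmax(len, lo), hi)
}

# apply substitution errors in bulk; returns modified sequences
apply_substitutions <- function(bases, qualities, model) {
  n <- length(bases)
  out <- bases
  for (i in seq_len(n)) {
    L <- nchar(bases[i])
    q <- utf8ToInt(qualities[i]) - 33L
    p <- model$mda_sub_rate +
      if (model$sub_error_rate_from_quality) 10^(-q / 10) else 0
    hit <- which(runif(L) < p)
    if (!length(hit)) next
    ch <- strsplit(out[i], "")[[1]]
    for (j in hit) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    out[i] <- paste(ch, collapse = "")
  }
  out
}

make_quality_strings <- function(lens, model) {
  vapply(lens, function(L) {
    q <- round(rnorm(L, model$base_quality, model$quality_sd))
    intToUtf8(pmin(pmax(q, 2L), 40L) + 33L)
  }, character(1))
}

#' Simulate MDA-biased 454-like reads from a community
#'
#' Read start positions are sampled proportionally to per-base
#' amplification gain times genome abundance; chimeric reads join two loci
#' at least 2 kb apart (second segment reverse-complemented with
#' probability 0.5, junction uniform within the read); substitution errors
#' are applied at the MDA polymerase rate plus the quality-derived rate.
#'
#' @param community Built community from [build_community()].
#' @param bias Named list of bias profiles, one per genome id; genomes
#'   without an entry get a uniform profile.
#' @param n_reads Number of reads (if `paired`, `n_reads`/2 pairs).
#' @param model A [read_model()].
#' @param paired Generate paired-end reads (outer span from the model;
#'   pairs are chimera-free).
#' @param barcode Optional barcode string prepended to every read (with
#'   maximal quality over the barcode bases).
#' @param sample_label Dataset-of-origin label recorded in `source`.
#' @param seed Integer seed.
#' @return List with `reads` (sequence-record tibble) and `truth` (tibble:
#'   read_id, genome, start, end, strand, is_chimera, start2, end2,
#'   strand2, junction; 0-based half-open, coordinates pre-error).
#' @export
simulate_reads <- function(community, bias = list(), n_reads,
                           model = read_model(), paired = FALSE,
                           barcode = NULL, sample_label = "sample",
                           seed = 1L) {
  stopifnot(n_reads > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "reads"))
  genomes <- community$genomes
  ng <- nrow(genomes)
  glens <- nchar(genomes$bases)
  profs <- lapply(seq_len(ng), function(i) {
    p <- bias[[genomes$id[i]]]
    if (is.null(p)) {
      tibble(start = 0L, end = glens[i], gain = 1)
    } else p
  })
  amp_mass <- vapply(profs, function(p) sum(p$gain * (p$end - p$start)),
                     numeric(1))
  w <- community$weights$cell_fraction * amp_mass
  dead <- which(community$weights$cell_fraction > 0 & amp_mass == 0)
  if (length(dead)) {
    abort(sprintf("genome '%s' has positive abundance but all-dropout profile",
                  genomes$id[dead[1]]))
  }

  draw_pos <- function(gi, len) {
    p <- profs[[gi]]
    segw <- p$gain * (p$end - p$start)
    si <- sample.int(nrow(p), 1, prob = segw)
    pos <- p$start[si] + floor(runif(1) * (p$end[si] - p$start[si]))
    min(max(0, pos), max(0, glens[gi] - len))
  }

  # truth columns are accumulated as flat vectors (one tibble at the end)
  if (paired) {
    npair <- floor(n_reads / 2)
    nr <- 2 * npair
    ids <- character(nr); seqs <- character(nr)
    mates <- character(nr)
    t_genome <- character(nr); t_start <- integer(nr); t_end <- integer(nr)
    t_strand <- character(nr); t_chim <- logical(nr)
    t_start2 <- rep(NA_integer_, nr); t_end2 <- rep(NA_integer_, nr)
    t_strand2 <- rep(NA_character_, nr); t_junc <- rep(NA_integer_, nr)
    lens <- sample_lengths(nr, model)
    gsel <- sample.int(ng, npair, replace = TRUE, prob = w)
    spans <- pmax(round(rnorm(npair, model$pair_span, model$sd_span)), 200)
    for (k in seq_len(npair)) {
      gi <- gsel[k]
      l1 <- lens[2 * k - 1]; l2 <- lens[2 * k]
      span <- min(spans[k], glens[gi])
      x <- draw_pos(gi, span)
      id1 <- sprintf("%s_p%06d_1", sample_label, k)
      id2 <- sprintf("%s_p%06d_2", sample_label, k)
      s1 <- substr(genomes$bases[gi], x + 1, x + l1)
      e2 <- x + span; s2s <- max(0, e2 - l2)
      s2 <- cpp_revcomp(substr(genomes$bases[gi], s2s + 1, e2))
      ids[2 * k - 1] <- id1; ids[2 * k] <- id2
      seqs[2 * k - 1] <- s1; seqs[2 * k] <- s2
      mates[2 * k - 1] <- id2; mates[2 * k] <- id1
      t_genome[2 * k - 1] <- genomes$id[gi]
      t_start[2 * k - 1] <- x; t_end[2 * k - 1] <- x + l1
      t_strand[2 * k - 1] <- "+"
      t_genome[2 * k] <- genomes$id[gi]
      t_start[2 * k] <- s2s; t_end[2 * k] <- e2
      t_strand[2 * k] <- "-"
    }
  } else {
    nr <- n_reads
    ids <- character(nr); seqs <- character(nr)
    mates <- rep(NA_character_, nr)
    t_genome <- character(nr); t_start <- integer(nr); t_end <- integer(nr)
    t_strand <- character(nr); t_chim <- logical(nr)
    t_start2 <- rep(NA_integer_, nr); t_end2 <- rep(NA_integer_, nr)
    t_strand2 <- rep(NA_character_, nr); t_junc <- rep(NA_integer_, nr)
    lens <- sample_lengths(nr, model)
    gsel <- sample.int(ng, nr, replace = TRUE, prob = w)
    chim <- runif(nr) < model$chimera_rate
    for (k in seq_len(nr)) {
      gi <- gsel[k]; L <- lens[k]
      ids[k] <- sprintf("%s_r%06d", sample_label, k)
      t_genome[k] <- genomes$id[gi]
      if (!chim[k] || glens[gi] < 5000) {
        x <- draw_pos(gi, L)
        strand <- if (runif(1) < 0.5) "+" else "-"
        s <- substr(genomes$bases[gi], x + 1, x + L)
        if (strand == "-") s <- cpp_revcomp(s)
        seqs[k] <- s
        t_start[k] <- x; t_end[k] <- x + nchar(s); t_strand[k] <- strand
      } else {
        j <- max(1, min(L - 1, floor(runif(1) * L)))
        l1 <- j; l2 <- L - j
        x1 <- draw_pos(gi, l1)
        repeat {
          x2 <- draw_pos(gi, l2)
          if (abs(x2 - x1) >= 2000) break
        }
        inv <- runif(1) < 0.5
        s1 <- substr(genomes$bases[gi], x1 + 1, x1 + l1)
        s2 <- substr(genomes$bases[gi], x2 + 1, x2 + l2)
        if (inv) s2 <- cpp_revcomp(s2)
        seqs[k] <- paste0(s1, s2)
        t_start[k] <- x1; t_end[k] <- x1 + l1; t_strand[k] <- "+"
        t_chim[k] <- TRUE
        t_start2[k] <- as.integer(x2); t_end2[k] <- as.integer(x2 + l2)
        t_strand2[k] <- if (inv) "-" else "+"
        t_junc[k] <- as.integer(j)
      }
    }
  }
  real_lens <- nchar(seqs)
  qual <- make_quality_strings(real_lens, model)
  seqs <- apply_substitutions(seqs, qual, model)
  if (!is.null(barcode)) {
    seqs <- paste0(barcode, seqs)
    qual <- paste0(strrep("I", nchar(barcode)), qual)
  }
  reads <- seq_tbl(ids, seqs, quality = qual,
                   source = rep(sample_label, length(ids)), mate = mates)
  truth <- tibble(read_id = ids, genome = t_genome, start = t_start,
                  end = t_end, strand = t_strand, is_chimera = t_chim,
                  start2 = t_start2, end2 = t_end2, strand2 = t_strand2,
                  junction = t_junc)
  list(reads = reads, truth = truth)
}
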