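# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite is hermetic.

rand_seq <- function(n, seed = 1, gc = 0.5) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# error-free reads tiling a genome at `depth`: systematic starts so the
# ends are covered, guaranteeing exact reconstructability
tiling_reads <- function(genome_bases, depth = 10, len = 400, seed = 1,
                         prefix = "r") {
  L <- nchar(genome_bases)
  step <- max(1, floor(len / depth))
  starts <- unique(c(seq(0, L - len, by = step), L - len))
  seq_tbl(sprintf("%s%05d", prefix, seq_along(starts)),
          substring(genome_bases, starts + 1, starts + len))
}

# mutate a sequence with substitutions at the given rate
mutate_seq <- function(bases, rate, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- strsplit(bases, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# independent Smith-Waterman oracle via Biostrings (both strands)
sw_oracle <- function(q, s, match = 2, mismatch = -3, gap_open = 5,
                      gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  fwd <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  rev <- Biostrings::pairwiseAlignment(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(q))),
    s, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  best <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) fwd else rev
  list(score = Biostrings::score(best),
       identity = Biostrings::nmatch(best) / Biostrings::nchar(best),
       strand = if (Biostrings::score(fwd) >= Biostrings::score(rev))
         "+" else "-")
}
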