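test_that("windowed GC agrees with the whole-genome value", {
  g <- simulate_genome(genome_spec(100000, 0.32, name = "g"), seed = 91)
  tr <- windowed_gc(g)
  expect_true(all(abs(tr$value - 0.32) < 0.05))
  # telescoping windows (step = window) average to the global GC
  tr2 <- windowed_gc(g, window = 1000, step = 1000)
  expect_lt(abs(mean(tr2$value) - gc_content(g$bases)), 0.001)

  gg <- seq_tbl("gg", paste0(strrep("G", 500), strrep("A", 1500)))
  tw <- windowed_gc(gg, window = 500, step = 500)
  expect_equal(tw$value[1], 1)
})

test_that("gc skew handles windows, zeros and mirror symmetry", {
  w <- seq_tbl("w", paste0("GGGGCC", strrep("A", 994)))
  tr <- gc_skew(w, window = 6, step = 6)
  expect_equal(tr$value[1], 1 / 3)

  at_only <- seq_tbl("at", strrep("AT", 500))
  expect_true(all(gc_skew(at_only, window = 100, step = 100)$value == 0))

  g <- simulate_genome(genome_spec(20000, 0.4), seed = 92)
  fwd <- gc_skew(g, window = 1000, step = 1000)
  rev <- gc_skew(seq_tbl("rc", revcomp(g$bases)),
                 window = 1000, step = 1000)
  expect_equal(fwd$value, -rev(rev$value), tolerance = 1e-12)
})

test_that("cumulative skew telescopes and peaks at a planted boundary", {
  gc1000 <- seq_tbl("g", paste0(strrep("G", 1000), strrep("C", 1000)))
  tr <- gc_skew(gc1000, window = 100, step = 100, cumulative = TRUE)
  expect_equal(max(tr$value), 1000)
  expect_equal(tr$end[which.max(tr$value)], 1000)
  # telescoping: final cumulative value = total G - C
  expect_equal(tr$value[nrow(tr)], 0)

  g <- simulate_genome(genome_spec(50000, 0.4), seed = 93)
  cum <- gc_skew(g, window = 1000, step = 1000, cumulative = TRUE)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(g$bases),
                                   c("G", "C"))
  expect_equal(cum$value[nrow(cum)], unname(f[1] - f[2]))
})

test_that("oligomer skew counts overlapping motifs on both mirrors", {
  a <- seq_tbl("a", paste0("GGGTGGGT", strrep("A", 92)))
  tr <- oligo_skew(a, window = 8, step = 8)
  expect_equal(tr$value[1], 1)
  b <- seq_tbl("b", paste0("ACCCACCC", strrep("A", 92)))
  expect_equal(oligo_skew(b, window = 8, step = 8)$value[1], -1)
  # overlapping occurrences are counted
  c3 <- seq_tbl("c", paste0("GGGGGT", strrep("A", 94)))
  expect_equal(oligo_skew(c3, motif = "GGG", window = 6, step = 6)$value[1],
               1)
  expect_error(oligo_skew(a, motif = "GATC"), "reverse complement")
})

test_that("single-base oligomer skew reduces to gc skew", {
  g <- simulate_genome(genome_spec(20000, 0.45), seed = 94)
  a <- oligo_skew(g, motif = "G", window = 1000, step = 1000,
                  cumulative = TRUE)
  b <- gc_skew(g, window = 1000, step = 1000, cumulative = TRUE)
  expect_equal(a$value, b$value)
})

test_that("transition finding ranks the planted composition switch first", {
  v <- c(10, 5, 0, 5, 10)
  tr <- tibble::tibble(element = "e", start = 0:4 * 100,
                       end = 1:5 * 100, value = v, statistic = "s")
  out <- find_transitions(tr)
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "minimum")
  expect_equal(out$position, 200)

  mono <- tibble::tibble(element = "e", start = 0:4 * 100, end = 1:5 * 100,
                         value = 1:5, statistic = "s")
  outm <- find_transitions(mono)
  expect_true(attr(outm, "no_internal_transition"))
  expect_equal(outm$kind, c("endpoint", "endpoint"))

  g <- simulate_genome(genome_spec(200000, 0.324,
                                   composition_switch = 100000),
                       seed = 95)
  cum <- gc_skew(g, window = 5000, step = 5000, cumulative = TRUE)
  top <- find_transitions(cum)[1, ]
  expect_lt(abs(top$position - 100000), 2 * 5000 + 1)
})

test_that("planted switches surface in cumulative GGGT skew", {
  g <- simulate_genome(genome_spec(200000, 0.324,
                                   composition_switch = 100000),
                       seed = 96)
  cum <- oligo_skew(g, motif = "GGGT", window = 5000, step = 5000,
                    cumulative = TRUE)
  top <- find_transitions(cum)[1, ]
  expect_lt(abs(top$position - 100000), 2 * 5000 + 1)
})

test_that("codon usage counts in frame and per mille", {
  cu <- codon_usage(seq_tbl("g", "ATGATGTAA"))
  expect_equal(cu$count[cu$codon == "ATG"], 2)
  expect_equal(cu$count[cu$codon == "TAA"], 1)
  expect_equal(cu$per_mille[cu$codon == "ATG"], 2000 / 3, tolerance = 1e-9)
  expect_equal(sum(cu$per_mille), 1000, tolerance = 1e-9)

  # concatenation invariance of counts
  c1 <- seq_tbl("a", "ATGAAATTTTAA")
  c2 <- seq_tbl("b", "ATGCCCGGGTGA")
  both <- dplyr::bind_rows(c1, c2)
  expect_equal(codon_usage(both)$count,
               codon_usage(c1)$count + codon_usage(c2)$count)

  expect_warning(codon_usage(seq_tbl("odd", "ATGA")), "truncating")
})

test_that("scrambling preserves composition but destroys codon structure", {
  set.seed(97)
  # codon-biased CDS: draw codons from a skewed codon distribution
  biased_cds <- function(n_genes, seed) {
    old <- .Random.seed
    set.seed(seed)
    codons <- c("ATG", "AAA", "GAT", "TTT", "GAA", "CAT")
    out <- vapply(seq_len(n_genes), function(i) {
      paste(sample(codons, 150, replace = TRUE,
                   prob = c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03)),
            collapse = "")
    }, character(1))
    .Random.seed <<- old
    seq_tbl(sprintf("g%02d_%d", seq_len(n_genes), seed), out)
  }
  a <- biased_cds(10, 1)
  cu_a <- codon_usage(a)
  # identical composition after scrambling, per CDS
  sc <- scrambled_control(a, seed = 2)
  expect_equal(
    Biostrings::letterFrequency(Biostrings::DNAStringSet(sc$bases),
                                c("A", "C", "G", "T")),
    Biostrings::letterFrequency(Biostrings::DNAStringSet(a$bases),
                                c("A", "C", "G", "T")),
    ignore_attr = TRUE)
  # distance to a same-codon-model CDS set stays below the distance to the
  # scrambled control, across seeds
  wins <- vapply(1:20, function(s) {
    other <- biased_cds(10, 100 + s)
    d_other <- codon_usage_distance(cu_a, codon_usage(other))
    d_scram <- codon_usage_distance(cu_a,
                                    codon_usage(scrambled_control(a, s)))
    d_scram > d_other
  }, logical(1))
  expect_true(all(wins))
})

test_that("codon distances are metrics in practice", {
  set.seed(98)
  tabs <- lapply(1:3, function(i) {
    codon_usage(seq_tbl(paste0("g", i), rand_seq(3 * 500, seed = i)))
  })
  d <- function(x, y) codon_usage_distance(x, y)
  expect_equal(d(tabs[[1]], tabs[[1]]), 0)
  expect_equal(d(tabs[[1]], tabs[[2]]), d(tabs[[2]], tabs[[1]]))
  expect_lte(d(tabs[[1]], tabs[[3]]),
             d(tabs[[1]], tabs[[2]]) + d(tabs[[2]], tabs[[3]]) + 1e-9)
  expect_gte(codon_usage_distance(tabs[[1]], tabs[[2]], method = "cosine"), 0)
})

test_that("annotation summaries reproduce published-style arithmetic", {
  # 2047 ORFs on 1,769,573 bases -> density 1.16; totals conserve
  genes <- dplyr::bind_rows(
    gene_table(sprintf("orf%04d", 1:2047), "e", (0:2046) * 800,
               (0:2046) * 800 + 700, category = "CDS"),
    gene_table(sprintf("ps%03d", 1:74), "e", 1700000 + (0:73) * 120,
               1700000 + (0:73) * 120 + 100, category = "pseudogene"),
    gene_table(sprintf("trna%02d", 1:42), "e2", (0:41) * 100,
               (0:41) * 100 + 80, category = "tRNA"),
    gene_table(sprintf("trna_cmp%d", 1:3), "e2", 5000 + (0:2) * 100,
               5000 + (0:2) * 100 + 80, category = "tRNA"),
    gene_table(sprintf("rrna%d", 1:4), "e2", 10000 + (0:3) * 1500,
               10000 + (0:3) * 1500 + 1400, category = "rRNA"),
    gene_table("ncrna", "e2", 20000, 20100, category = "other_RNA"))
  s <- annotation_summary(genes, assembly_length = 1769573)
  expect_equal(s$orf_density, 1.16)
  expect_equal(s$orfs, 2047)
  expect_equal(s$pseudogenes, 74)
  expect_equal(s$rna_genes, 50)
  expect_equal(s$total_genes, 2171)
  expect_equal(sum(genes$category == "tRNA"), 45)

  # coding fraction via interval union, overlaps and nesting collapsed
  g2 <- dplyr::bind_rows(
    gene_table("a", "e", 0, 500),
    gene_table("b", "e", 400, 700),           # overlaps a
    gene_table("c", "e", 450, 460),           # nested
    gene_table("d", "e", 800, 930))
  s2 <- annotation_summary(g2, assembly_length = 1000)
  expect_equal(s2$coding_fraction, 0.83)
})
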