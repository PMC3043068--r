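test_that("self- and strand-alignment behave as expected", {
  s <- rand_seq(100, seed = 1)
  h <- local_align(seq_tbl("q", s), seq_tbl("s", s))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0, 100, 0, 100))

  hr <- local_align(seq_tbl("q", revcomp(s)), seq_tbl("s", s))
  expect_equal(hr$strand, "-")
  expect_equal(hr$identity, 1)
})

test_that("five substitutions in a 100-mer give identity 0.95", {
  s <- rand_seq(100, seed = 2)
  ch <- strsplit(s, "")[[1]]
  pos <- c(10, 30, 50, 70, 90)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  q <- paste(ch, collapse = "")
  h <- local_align(seq_tbl("q", q), seq_tbl("s", s), mode = "exact")
  orc <- sw_oracle(q, s)
  expect_equal(max(h$score), orc$score)
  best <- h[which.max(h$score), ]
  expect_equal(best$identity, orc$identity)
  expect_equal(best$identity, 0.95, tolerance = 0.011)
})

test_that("exact mode equals full Smith-Waterman on random seeded pairs", {
  set.seed(99)
  for (i in 1:40) {
    q <- rand_seq(sample(60:200, 1), seed = 1000 + i)
    s <- rand_seq(sample(60:200, 1), seed = 2000 + i)
    # plant a noisy shared segment so a seeded 11-mer exists
    seg <- substr(q, 15, 15 + sample(30:60, 1))
    seg <- mutate_seq(seg, 0.04, seed = 3000 + i)
    at <- sample(nchar(s) - 5, 1)
    s <- paste0(substr(s, 1, at), seg, substr(s, at + 1, nchar(s)))
    h <- local_align(seq_tbl("q", q), seq_tbl("s", s), mode = "exact")
    orc <- sw_oracle(q, s)
    if (orc$score >= 50) {
      expect_equal(max(h$score), orc$score,
                   info = sprintf("case %d", i))
    }
  }
})

test_that("seeded heuristic agrees with exact DP on planted homology", {
  g <- rand_seq(20000, seed = 5)
  for (i in 1:10) {
    frag <- substr(g, i * 1500 + 1, i * 1500 + 300)
    frag <- mutate_seq(frag, 0.05, seed = i)
    hs <- local_align(seq_tbl("q", frag), seq_tbl("s", g), mode = "seeded")
    orc <- sw_oracle(frag, g)
    expect_gt(nrow(hs), 0)
    best <- hs[which.max(hs$score), ]
    # gapless planted divergence: heuristic must find the full-score hit
    expect_gte(best$score, orc$score * 0.98)
  }
})

test_that("map_reads enforces the 90% / 40-base acceptance rule", {
  ref <- seq_tbl("ref", rand_seq(5000, seed = 6))
  ok_read <- substr(ref$bases, 1001, 1400)
  mp <- map_reads(seq_tbl("r1", ok_read), ref)
  expect_equal(mp$mapped$s_start, 1000)
  expect_equal(mp$mapped$identity, 1)

  # 39-base perfect hit fails the length threshold
  short <- substr(ref$bases, 2001, 2039)
  mp2 <- map_reads(seq_tbl("r2", short), ref,
                   scoring = align_scoring(min_score = 20))
  expect_equal(nrow(mp2$mapped), 0)
  expect_equal(mp2$unmapped, "r2")

  # ~50-base hit at 88% identity fails the identity threshold; mismatches
  # are spread so no 40-column window clears 90% either
  seg <- substr(ref$bases, 3001, 3050)
  ch <- strsplit(seg, "")[[1]]
  for (p in c(4, 12, 20, 28, 36, 44)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  mp3 <- map_reads(seq_tbl("r3", paste(ch, collapse = "")), ref,
                   scoring = align_scoring(min_score = 20))
  expect_equal(nrow(mp3$mapped), 0)
})

test_that("mapping is monotone in the acceptance criteria", {
  comm <- build_community(
    community_spec(genome_spec(30000, 0.4, name = "t"), list(),
                   target_fraction = 1), seed = 7)
  sim <- simulate_reads(comm, n_reads = 200, seed = 8)
  strict <- map_reads(sim$reads, comm$genomes,
                      criteria = map_criteria(0.95, 100))
  loose <- map_reads(sim$reads, comm$genomes,
                     criteria = map_criteria(0.90, 40))
  expect_true(all(strict$mapped$query_id %in% loose$mapped$query_id))
})

test_that("mapping reverse-complemented reads flips strand only", {
  ref <- seq_tbl("ref", rand_seq(3000, seed = 9))
  reads <- seq_tbl(c("a", "b"),
                   c(substr(ref$bases, 101, 500),
                     substr(ref$bases, 1501, 1900)))
  fwd <- map_reads(reads, ref)$mapped
  rc <- seq_tbl(reads$id, revcomp(reads$bases))
  rev <- map_reads(rc, ref)$mapped
  expect_equal(fwd$identity, rev$identity)
  expect_true(all(fwd$strand != rev$strand))
  expect_equal(fwd$s_start, rev$s_start)
})

test_that("constructed chimeras are flagged with two-segment evidence", {
  g <- rand_seq(600000, seed = 10)
  ref <- seq_tbl("ref", g)
  chim <- paste0(substr(g, 10001, 10200),
                 substr(g, 500001, 500200))
  plain <- substr(g, 250001, 250400)
  calls <- flag_chimeras(seq_tbl(c("c", "p"), c(chim, plain)), ref)
  expect_true(calls$is_chimeric[calls$read_id == "c"])
  expect_false(calls$is_chimeric[calls$read_id == "p"])
  ev <- calls[calls$read_id == "c", ]
  expect_true(abs(ev$s_start1 - ev$s_start2) > 2000)
})

test_that("chimera calls are precise, and near-complete on callable reads", {
  comm <- build_community(
    community_spec(genome_spec(200000, 0.324, name = "t"), list(),
                   target_fraction = 1), seed = 11)
  sim <- simulate_reads(comm, n_reads = 20000,
                        model = read_model(chimera_rate = 0.02), seed = 12)
  calls <- flag_chimeras(sim$reads, comm$genomes)
  tr <- sim$truth[match(calls$read_id, sim$truth$read_id), ]
  truth <- tr$is_chimera
  tp <- sum(calls$is_chimeric & truth)
  fp <- sum(calls$is_chimeric & !truth)
  expect_gte(tp / (tp + fp), 0.95)
  # the 80%-single-hit-cover rule makes junctions outside the central
  # 20-80% of the read uncallable by construction, so recall is measured
  # on the callable set; overall recall has a geometric ceiling of ~0.6
  # with a junction uniform within the read
  rlen <- nchar(sim$reads$bases)[match(calls$read_id, sim$reads$id)]
  seg1 <- tr$junction
  callable <- truth & !is.na(seg1) &
    seg1 >= pmax(40, 0.2 * rlen) & (rlen - seg1) >= pmax(40, 0.2 * rlen)
  recall_callable <- sum(calls$is_chimeric & callable) / sum(callable)
  expect_gte(recall_callable, 0.80)
  # and overall recall is consistent with that geometry
  expect_gte(tp / sum(truth), 0.45)
})

test_that("hits export in outfmt-6 column order with 1-based coordinates", {
  s <- rand_seq(200, seed = 13)
  h <- local_align(seq_tbl("q", s), seq_tbl("s", s))
  tmp <- withr::local_tempfile()
  export_hits_tsv(h, tmp)
  row <- strsplit(readLines(tmp), "\t")[[1]]
  expect_equal(length(row), 12)
  expect_equal(row[1:2], c("q", "s"))
  expect_equal(as.numeric(row[7]), 1)   # qstart 1-based
  expect_equal(as.numeric(row[8]), 200)
  expect_equal(row[11], "NA")           # no E-value model
})
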