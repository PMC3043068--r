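test_that("simulated genomes hit their target composition", {
  g <- simulate_genome(genome_spec(100000, 0.324, name = "g"), seed = 1)
  # binomial oracle: 3 sigma ~ 0.0044 at this length
  expect_lt(abs(gc_content(g$bases) - 0.324), 0.01)

  pure <- simulate_genome(genome_spec(500, 1.0, name = "gc1"), seed = 2)
  expect_true(grepl("^[GC]+$", pure$bases))

  a <- simulate_genome(genome_spec(5000, 0.4), seed = 7)
  b <- simulate_genome(genome_spec(5000, 0.4), seed = 7)
  expect_identical(a$bases, b$bases)
})

test_that("composition switch skews G:C while conserving total GC", {
  g <- simulate_genome(genome_spec(200000, 0.4, composition_switch = 100000),
                       seed = 3)
  pre <- substr(g$bases, 1, 100000)
  post <- substr(g$bases, 100001, 200000)
  cnt <- function(s, b) lengths(gregexpr(b, s, fixed = TRUE))
  expect_lt(abs(cnt(pre, "G") / (cnt(pre, "G") + cnt(pre, "C")) - 0.5), 0.02)
  expect_gt(cnt(post, "G") / (cnt(post, "G") + cnt(post, "C")), 0.55)
  expect_lt(abs(gc_content(post) - 0.4), 0.02)
})

test_that("bias profiles tile the genome and respect degenerate settings", {
  p <- simulate_bias_profile(100000, seed = 4)
  expect_equal(p$start[1], 0)
  expect_equal(p$end[nrow(p)], 100000)
  expect_true(all(p$start[-1] == head(p$end, -1)))  # no gaps, no overlap

  flat <- simulate_bias_profile(100000, sigma = 0, dropout_quantile = 0,
                                seed = 5)
  expect_true(all(flat$gain == flat$gain[1]))
})

test_that("independent cells have uncorrelated amplification profiles", {
  # rank correlation of per-base gain between profile pairs; averaged over
  # pairs because a single 200 kb profile has only ~20 effective segments
  per_base_gain <- function(seed) {
    p <- simulate_bias_profile(1000000, seed = seed)
    rep(p$gain, p$end - p$start)[seq(1, 1000000, by = 500)]
  }
  rs <- vapply(1:8, function(k) {
    cor(per_base_gain(2 * k - 1), per_base_gain(2 * k),
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("default bias parameters leave ~60% recoverable at 20x", {
  fr <- vapply(1:100, function(s)
    recoverable_fraction(simulate_bias_profile(200000, seed = s)),
    numeric(1))
  expect_lt(abs(mean(fr) - 0.60), 0.05)
  # bulk profile leaves essentially everything recoverable
  bulk <- vapply(1:20, function(s)
    recoverable_fraction(bulk_bias_profile(200000, seed = s)),
    numeric(1))
  expect_gt(mean(bulk), 0.97)
})

test_that("coverage union of independent cells follows 1-(1-c)^k", {
  k <- 5
  reps <- 20
  grid <- seq(1, 200000, by = 200)
  per_cell <- c(); unions <- c()
  for (r in seq_len(reps)) {
    cov <- rep(FALSE, length(grid))
    for (c in seq_len(k)) {
      p <- simulate_bias_profile(200000, seed = r * 100 + c)
      seg <- recoverable_segments(p)
      idx <- findInterval(grid - 1, seg$start)
      rec <- seg$recoverable[idx]
      per_cell <- c(per_cell, mean(rec))
      cov <- cov | rec
    }
    unions <- c(unions, mean(cov))
  }
  c_hat <- mean(per_cell)
  expected <- 1 - (1 - c_hat)^k
  se <- sd(unions) / sqrt(reps)
  expect_lt(abs(mean(unions) - expected), 3 * se + 0.02)
})

test_that("simulated reads honour chimera and purity settings", {
  comm <- build_community(default_community(50000L), seed = 1)
  no_chim <- simulate_reads(comm, n_reads = 500,
                            model = read_model(chimera_rate = 0), seed = 2)
  expect_false(any(no_chim$truth$is_chimera))

  pure <- build_community(
    community_spec(genome_spec(50000, 0.324, name = "t"), list(),
                   target_fraction = 1), seed = 1)
  ps <- simulate_reads(pure, n_reads = 300, seed = 3)
  expect_true(all(ps$truth$genome == "t"))
})

test_that("chimera fraction matches the binomial oracle", {
  comm <- build_community(
    community_spec(genome_spec(100000, 0.324, name = "t"), list(),
                   target_fraction = 1), seed = 1)
  sim <- simulate_reads(comm, n_reads = 20000, seed = 4)
  frac <- mean(sim$truth$is_chimera)
  # binomial 3 sigma at n = 20000, p = 0.01 is 0.0021
  expect_lt(abs(frac - 0.01), 0.003)
  # chimeric truth records carry two loci >= 2 kb apart
  ch <- sim$truth[sim$truth$is_chimera, ]
  expect_true(all(!is.na(ch$start2)))
  expect_true(all(abs(ch$start2 - ch$start) >= 2000))
})

test_that("read GC dispersion matches the binomial expectation", {
  comm <- build_community(
    community_spec(genome_spec(100000, 0.324, name = "t"), list(),
                   target_fraction = 1), seed = 2)
  sim <- simulate_reads(comm, n_reads = 2000,
                        model = read_model(sd_len = 0, chimera_rate = 0,
                                           mda_sub_rate = 0,
                                           sub_error_rate_from_quality = FALSE),
                        seed = 5)
  h <- gc_histogram(sim$reads)
  expected_sd <- sqrt(0.324 * 0.676 / 400)
  expect_lt(abs(h$dispersion - expected_sd) / expected_sd, 0.2)
})

test_that("read simulation is byte-deterministic under a seed", {
  comm <- build_community(default_community(50000L), seed = 6)
  a <- simulate_reads(comm, n_reads = 300, seed = 11)
  b <- simulate_reads(comm, n_reads = 300, seed = 11)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  tmpa <- withr::local_tempfile(); tmpb <- withr::local_tempfile()
  write_fastq(a$reads, tmpa); write_fastq(b$reads, tmpb)
  expect_identical(readLines(tmpa), readLines(tmpb))
})

test_that("paired reads have symmetric pairing and correct geometry", {
  comm <- build_community(
    community_spec(genome_spec(100000, 0.4, name = "t"), list(),
                   target_fraction = 1), seed = 3)
  sim <- simulate_reads(comm, n_reads = 400, paired = TRUE, seed = 7)
  rd <- sim$reads
  expect_true(all(!is.na(rd$mate)))
  expect_identical(rd$mate[match(rd$mate, rd$id)], rd$id)
  # outer spans close to the library span
  tr <- sim$truth
  fwd <- tr[tr$strand == "+", ]; rev <- tr[tr$strand == "-", ]
  spans <- rev$end[match(sub("_1$", "_2", fwd$read_id), rev$read_id)] -
    fwd$start
  expect_lt(abs(mean(spans, na.rm = TRUE) - 3000), 100)
})

test_that("all-dropout profiles for an abundant genome are rejected", {
  comm <- build_community(
    community_spec(genome_spec(50000, 0.4, name = "t"), list(),
                   target_fraction = 1), seed = 4)
  dead <- tibble::tibble(start = 0L, end = 50000L, gain = 0)
  expect_error(
    simulate_reads(comm, bias = list(t = dead), n_reads = 10, seed = 1),
    "dropout")
})
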