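aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n, seed) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(aa_alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(p, rate, seed) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- strsplit(p, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa_alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}

test_that("identical proteomes give complete high-confidence RBH", {
  prots <- seq_tbl(sprintf("p%02d", 1:10),
                   vapply(1:10, function(i) rand_protein(120, i),
                          character(1)))
  other <- prots
  other$id <- sub("p", "q", other$id)
  pairs <- rbh(prots, other)
  expect_equal(nrow(pairs), 10)
  expect_true(all(pairs$identity_fwd == 1))
  expect_true(all(pairs$confidence == "high"))
  expect_equal(pairs$gene_b, sub("p", "q", pairs$gene_a))
})

test_that("planted orthologs are recovered among decoys", {
  planted <- vapply(1:8, function(i) rand_protein(150, 200 + i),
                    character(1))
  a <- seq_tbl(c(sprintf("a%02d", 1:8), sprintf("adecoy%d", 1:4)),
               c(planted,
                 vapply(1:4, function(i) rand_protein(150, 300 + i),
                        character(1))))
  b <- seq_tbl(c(sprintf("b%02d", 1:8), sprintf("bdecoy%d", 1:4)),
               c(vapply(seq_along(planted), function(i)
                 mutate_protein(planted[i], 0.2, 400 + i), character(1)),
                 vapply(1:4, function(i) rand_protein(150, 500 + i),
                        character(1))))
  pairs <- rbh(a, b)
  found <- pairs[grepl("^a\\d", pairs$gene_a), ]
  expect_equal(nrow(found), 8)
  expect_equal(found$gene_b, sub("a", "b", found$gene_a))
  expect_false(any(grepl("decoy", pairs$gene_a) &
                     !grepl("decoy", pairs$gene_b)))
})

test_that("rbh is symmetric and applies the 60% coverage rule", {
  core <- rand_protein(60, 600)
  # query gene twice the homologous region: forward coverage 50% -> low
  a <- seq_tbl("a1", paste0(core, rand_protein(60, 601)))
  b <- seq_tbl("b1", core)
  pairs <- rbh(a, b)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$confidence, "low")
  expect_lt(pairs$coverage_fwd, 0.6)

  # symmetry: swapping the gene sets swaps the roles
  prots <- seq_tbl(sprintf("p%d", 1:5),
                   vapply(1:5, function(i) rand_protein(100, 700 + i),
                          character(1)))
  qrots <- seq_tbl(sprintf("q%d", 1:5),
                   vapply(1:5, function(i)
                     mutate_protein(rand_protein(100, 700 + i), 0.1,
                                    800 + i), character(1)))
  ab <- rbh(prots, qrots)
  ba <- rbh(qrots, prots)
  expect_setequal(paste(ab$gene_a, ab$gene_b),
                  paste(ba$gene_b, ba$gene_a))
})

test_that("corresponding-region ANI matches construction", {
  g <- seq_tbl("g", rand_seq(50000, seed = 101))
  self <- ani_corresponding(g, g)
  expect_equal(self$corresponding_bases, 50000)
  expect_equal(self$identity_corresponding, 1)
  expect_equal(self$whole_genome_identity, 1)

  div <- seq_tbl("d", mutate_seq(g$bases, 0.05, seed = 102))
  rep5 <- ani_corresponding(div, g)
  expect_gt(rep5$corresponding_bases / 50000, 0.95)
  expect_lt(abs(rep5$identity_corresponding - 0.95), 0.005)

  stranger <- seq_tbl("s", rand_seq(50000, seed = 103))
  far <- ani_corresponding(stranger, g)
  expect_lt(far$corresponding_bases / 50000, 0.01)
})

test_that("whole-genome identity applies the 25% floor formula", {
  # worked example: corresponding 398,085 at 67.4%, reference 2,045,086
  rep <- ani_report(398085, 0.674, 2045086, floor_identity = 0.25)
  expect_equal(round(rep$whole_genome_identity * 100, 1), 33.3)

  # no floor contribution when everything corresponds
  expect_equal(whole_genome_identity(
    ani_report(1000, 0.8, 1000)), 0.8)
  # all floor when nothing corresponds
  expect_equal(whole_genome_identity(ani_report(0, 0, 1000)), 0.25)
  # monotone in corresponding bases when identity > floor
  vals <- vapply(seq(0, 1000, 100), function(cb)
    whole_genome_identity(ani_report(cb, 0.9, 1000)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("novelty tracks are bounded and reference-monotone", {
  g <- rand_seq(30000, seed = 104)
  target <- seq_tbl("t", g)
  # ref1 matches the first two thirds, ref2 the middle third
  ref1 <- seq_tbl("r1", substr(g, 1, 20000))
  ref2 <- seq_tbl("r2", substr(g, 10001, 20000))
  nv <- novelty_track(target, dplyr::bind_rows(ref1, ref2), window = NULL)
  expect_true(all(nv$novelty >= 0 & nv$novelty <= 2))
  # identical to both references in the middle third -> novelty 0
  expect_equal(mean(nv$novelty[12000:18000]), 0, tolerance = 0.01)
  # no hits to either reference in the last third -> novelty 2
  expect_equal(mean(nv$novelty[22000:30000]), 2, tolerance = 0.01)
  # covered by ref1 only -> novelty 1
  expect_equal(mean(nv$novelty[2000:8000]), 1, tolerance = 0.01)
  # depth counts covering hits
  expect_gte(mean(nv$depth[12000:18000]), 2 - 0.01)

  # adding a reference never increases novelty
  nv1 <- novelty_track(target, ref1, window = NULL)
  expect_true(all(nv$novelty <= nv1$novelty + 1 + 1e-9))
  one_vs_two <- (2 - nv$novelty) >= (1 - nv1$novelty) - 1e-9
  expect_true(all(one_vs_two))

  tracks <- novelty_track(target, dplyr::bind_rows(ref1, ref2),
                          window = 1000)
  expect_s3_class(tracks$novelty, "tbl_df")
  expect_equal(nrow(tracks$novelty), 30)
})

test_that("microheterogeneity recovers planted within-population variation", {
  g <- rand_seq(40000, seed = 105)
  mk_assembly <- function(bases, label) {
    new_assembly(seq_tbl(paste0(label, "_c1"), bases))
  }
  same <- microheterogeneity(list(a = mk_assembly(g, "a"),
                                  b = mk_assembly(g, "b")))
  expect_equal(same$ani, 1)
  expect_equal(same$snps, 0)

  # 0.1% planted variants: the headline 99.9% regime; oracle = the realized
  # number of substituted positions
  v <- mutate_seq(g, 0.001, seed = 106)
  realized <- sum(strsplit(g, "")[[1]] != strsplit(v, "")[[1]])
  pair <- microheterogeneity(list(a = mk_assembly(g, "a"),
                                  b = mk_assembly(v, "b")))
  expect_lt(abs(pair$ani - (1 - realized / 40000)), 0.0002)
  expect_lt(abs(pair$ani - 0.999), 0.001)
  expect_gt(pair$snps_per_mb, 500)
  expect_lt(pair$snps_per_mb, 1500)
})

test_that("expected-error budgets follow the Phred closed forms", {
  # 1000 bases at Q40 -> 0.1 expected errors
  eb <- expected_errors(n_low_quality_bases = 0, n_high_quality_bases = 1000)
  expect_equal(eb$expected_errors_high_tier, 0.1)

  # 5904 bases at Q10 contribute 590.4 from the low tier
  eb2 <- expected_errors(n_low_quality_bases = 5904, assumed_q_low = 10,
                         n_high_quality_bases = 1769573 - 5904,
                         assumed_q_high = 40,
                         assembly_length = 1769573)
  expect_equal(eb2$expected_errors_low_tier, 590.4)
  expect_equal(eb2$expected_errors_two_tier,
               590.4 + (1769573 - 5904) * 1e-4)
  # MDA contribution: 1e-5 * 1,769,573 < 20 bases
  expect_equal(eb2$mda_expected_errors, 17.69573)
  expect_lt(eb2$mda_expected_errors, 20)

  # exact form equals the per-base sum and is additive over disjoint sets
  q1 <- int_to_phred(list(c(10, 20, 30)))
  q2 <- int_to_phred(list(c(40, 40)))
  e1 <- expected_errors(quality_strings = q1)$expected_errors_exact
  e2 <- expected_errors(quality_strings = q2)$expected_errors_exact
  both <- expected_errors(quality_strings = c(q1, q2))$expected_errors_exact
  expect_equal(e1, 0.1 + 0.01 + 0.001)
  expect_equal(both, e1 + e2)
})
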