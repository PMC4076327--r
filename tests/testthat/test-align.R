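test_that("lambda matches an independent bisection oracle to 1e-9", {
  oracle_lambda <- function(reward, penalty, p_match = 0.25) {
    f <- function(lam) {
      p_match * exp(lam * reward) + (1 - p_match) * exp(lam * penalty) - 1
    }
    lo <- 1e-12; hi <- 10
    while (f(hi) < 0) hi <- hi * 2
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (rp in list(c(5, -4), c(1, -2), c(2, -3), c(1, -3))) {
    k <- estimate_karlin(scoring_scheme(reward = rp[1], penalty = rp[2]))
    expect_equal(k$lambda, oracle_lambda(rp[1], rp[2]), tolerance = 1e-9,
                 info = paste(rp, collapse = "/"))
    expect_gt(k$K, 0); expect_lt(k$K, 1)
    expect_gt(k$H, 0)
  }
})

test_that("scaling all scores by 2 halves lambda", {
  k1 <- estimate_karlin(scoring_scheme(reward = 5, penalty = -4))
  k2 <- estimate_karlin(scoring_scheme(reward = 10, penalty = -8))
  expect_equal(k2$lambda, k1$lambda / 2, tolerance = 1e-9)
})

test_that("a non-negative expected score is rejected", {
  expect_error(estimate_karlin(scoring_scheme(reward = 5, penalty = -1)),
               "invalid scoring scheme")
  expect_error(scoring_scheme(penalty = 1), "penalty")
  expect_error(scoring_scheme(reward = 0), "reward")
  expect_error(scoring_scheme(word_size = 3), "word_size")
})

test_that("self-alignment scores 5L and one mismatch costs 9", {
  set.seed(61)
  s <- random_dna(30)
  h <- align_pair(s, s, both_strands = FALSE)
  expect_equal(h$score, 150L)
  expect_equal(h$identity, 1)
  expect_equal(h$q_start, 0L); expect_equal(h$q_end, 30L)
  s2 <- s
  substr(s2, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 15, 15))[1]
  h2 <- align_pair(s, s2, both_strands = FALSE)
  expect_equal(h2$score, 141L) # 29*5 - 4
})

test_that("seeded scores equal the full affine Smith-Waterman oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(62)
  for (i in 1:25) {
    core <- random_dna(60)
    a <- paste0(random_dna(sample(20:120, 1)), core,
                random_dna(sample(20:120, 1)))
    b <- paste0(random_dna(sample(20:120, 1)), core,
                random_dna(sample(20:120, 1)))
    h <- align_pair(a, b, both_strands = FALSE)
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 8, gapExtension = 6)
    expect_equal(h$score[1], Biostrings::score(pw), info = i)
  }
})

test_that("edit-string rescoring reproduces every reported score", {
  set.seed(63)
  for (i in 1:15) {
    a <- random_dna(250)
    b <- make_ortholog_pair(seq_record("a", a), divergence = 0.2,
                            indel_rate = 0.01, seed = 9000 + i)$seq
    h <- align_pair(a, b)
    for (j in seq_len(nrow(h))) {
      expect_equal(rescore_edit(h$edit[j]), h$score[j])
    }
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(64)
  for (i in 1:8) {
    a <- random_dna(200)
    b <- make_ortholog_pair(seq_record("a", a), divergence = 0.25,
                            indel_rate = 0.02, seed = 9100 + i)$seq
    ha <- align_pair(a, b); hb <- align_pair(b, a)
    expect_equal(max(ha$score), max(hb$score), info = i)
  }
})

test_that("E-values decrease strictly in score and scale with lengths", {
  k <- estimate_karlin(scoring_scheme())
  e <- karlin_evalue(c(100, 150, 200), 600, 600, k)
  expect_true(all(diff(e) < 0))
  expect_equal(karlin_evalue(100, 1200, 600, k),
               2 * karlin_evalue(100, 600, 600, k))
})

test_that("a block aligned to itself is far below the 1e-15 cutoff", {
  rec <- random_background(600, seed = 66, id = "b")
  h <- align_pair(rec, rec)
  expect_lt(min(h$evalue), 1e-15)
})

test_that("unrelated random blocks produce no hits at 1e-15", {
  set.seed(67)
  n_hit <- 0L
  for (i in 1:10) {
    a <- data.frame(id = "a", seq = random_dna(600))
    b <- data.frame(id = "b", seq = random_dna(600))
    n_hit <- n_hit + nrow(all_vs_all(a, b, evalue_max = 1e-15))
  }
  expect_equal(n_hit, 0L)
})

test_that("reciprocal homolog logic keeps only mutual best partners", {
  hits_ab <- data.frame(
    query_id = c("a1", "a1", "a2"), subject_id = c("b1", "b2", "b2"),
    score = c(300L, 200L, 250L), s_start = c(0L, 0L, 0L))
  hits_ba <- data.frame(
    query_id = c("b1", "b2"), subject_id = c("a1", "a3"),
    score = c(280L, 240L), s_start = c(0L, 0L))
  rec <- reciprocal_homologs(hits_ab, hits_ba)
  # a1<->b1 mutual; a2->b2 but b2's best is a3, so excluded
  expect_equal(rec$id_a, "a1")
  expect_equal(rec$id_b, "b1")
})

test_that("a planted one-to-one ortholog set is recovered reciprocally", {
  bench <- make_ortholog_benchmark(n = 12, block_len = 500,
                                   divergence = 0.25, indel_rate = 0.01,
                                   seed = 68)
  hits_ab <- all_vs_all(bench$blocks_a, bench$blocks_b, evalue_max = 1e-15)
  hits_ba <- all_vs_all(bench$blocks_b, bench$blocks_a, evalue_max = 1e-15)
  rec <- reciprocal_homologs(hits_ab, hits_ba)
  got <- rec[order(rec$id_a), ]
  want <- bench$truth[order(bench$truth$id_a), ]
  expect_equal(got$id_a, want$id_a)
  expect_equal(got$id_b, want$id_b)
})

test_that("sequences shorter than the word size yield no hits", {
  expect_equal(nrow(align_pair("ACGTACGT", "ACGTACGT")), 0L)
})
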