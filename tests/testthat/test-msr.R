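test_that("tandem repeats on simple constructions", {
  tr <- find_tandem_repeats("CACACACA")
  expect_true(any(tr$unit_seq == "CA" & tr$copies == 4 &
                    tr$start == 0 & tr$end == 8))
  expect_true(any(tr$unit_seq == "CACA" & tr$copies == 2))
  expect_equal(nrow(find_tandem_repeats("ACGT")), 0L)
  expect_equal(nrow(find_tandem_repeats("")), 0L)
})

test_that("exhaustive semantics cover the shifted seed that a single regex pass misses", {
  cov_ex <- which(msr_mask("ACGTACGTA")) - 1L
  expect_equal(cov_ex, 0:8)
  tr_re <- find_tandem_repeats("ACGTACGTA", semantics = "regex_single_pass")
  cov_re <- which(msr_mask(seq_record("r", "ACGTACGTA"), tr_re)) - 1L
  expect_equal(cov_re, 0:7)
})

test_that("tract invariants hold: whole copies, unit bounds, sequence match", {
  set.seed(91)
  for (i in 1:10) {
    s <- random_dna(200, with_n = TRUE)
    tr <- find_tandem_repeats(s)
    if (nrow(tr) == 0L) next
    expect_true(all(tr$end - tr$start == tr$unit_len * tr$copies))
    expect_true(all(tr$unit_len >= 2 & tr$unit_len <= 50))
    expect_true(all(tr$copies >= 2))
    for (j in seq_len(nrow(tr))) {
      span <- substr(s, tr$start[j] + 1, tr$end[j])
      expect_equal(span, strrep(tr$unit_seq[j], tr$copies[j]))
    }
  }
})

test_that("mask equals the brute-force doubling oracle on random sequences", {
  set.seed(92)
  for (i in 1:25) {
    s <- random_dna(150, with_n = i %% 2 == 0)
    expect_equal(which(msr_mask(s)) - 1L, oracle_tandem_cover(s), info = i)
  }
})

test_that("mask equals the oracle on every {A,C} string up to length 12", {
  for (s in ac_strings(2, 12)) {
    got <- which(msr_mask(s)) - 1L
    want <- oracle_tandem_cover(s)
    if (!identical(got, want)) {
      fail(sprintf("coverage mismatch on %s", s))
    }
  }
  succeed()
})

test_that("exhaustive coverage is a superset of single-pass regex coverage", {
  set.seed(93)
  for (i in 1:40) {
    s <- random_dna(200)
    rec <- seq_record("r", s)
    cov_ex <- msr_mask(rec)
    cov_re <- msr_mask(rec, find_tandem_repeats(rec,
                                                semantics = "regex_single_pass"))
    expect_true(all(which(cov_re) %in% which(cov_ex)), info = i)
  }
})

test_that("N breaks tracts", {
  # the (CA)2 doubles on each side of the N are real; nothing spans the N
  tr0 <- find_tandem_repeats("CACANCACA")
  expect_true(all(tr0$end <= 4 | tr0$start >= 5))
  expect_equal(nrow(find_tandem_repeats("CANCA")), 0L)
  tr <- find_tandem_repeats("CACACANCACACA")
  expect_true(all(tr$end <= 6 | tr$start >= 7))
})

test_that("mask is the union of tract intervals", {
  rec <- seq_record("r", strrep("T", 12))
  tracts <- data.frame(seq_id = "r", start = c(0L, 4L), end = c(8L, 12L),
                       unit_len = c(2L, 2L), unit_seq = "TT",
                       copies = c(4L, 4L))
  expect_equal(sum(msr_mask(rec, tracts)), 12L)
  expect_equal(sum(msr_mask(rec, tracts[0, ])), 0L)
})

test_that("msr_content is a fraction of the window and validates bounds", {
  rec <- seq_record("r", strrep("CA", 200))
  expect_equal(msr_content(rec, c(0, 400)), 1.0)
  set.seed(94)
  s1 <- random_dna(200); s2 <- random_dna(300)
  rec1 <- seq_record("a", s1); rec2 <- seq_record("b", s2)
  cc <- msr_content(seq_record("c", paste0(s1, s2)),
                    c(0, 500))
  c1 <- msr_content(rec1, c(0, 200)); c2 <- msr_content(rec2, c(0, 300))
  # concatenation content lies near the length-weighted mean (joins can only
  # add coverage at the seam)
  expect_gte(cc, (200 * c1 + 300 * c2) / 500 - 1e-9)
  expect_error(msr_content(rec1, c(0, 201)), "outside record")
  expect_error(msr_content(rec1, c(-1, 100)), "outside record")
})

test_that("cluster-centred windows sit at the site-cluster midpoint and clip", {
  nee <- data.frame(twist_start = 280L, twist_end = 287L,
                    dorsal_start = 297L, dorsal_end = 306L,
                    suh_start = 306L, suh_end = 314L)
  rec <- seq_record("r", strrep("A", 600))
  w <- center_window_on_cluster(nee, rec, 400)
  expect_equal(w$interval$start, (280 + 314) %/% 2 - 200)
  expect_equal(w$interval$end - w$interval$start, 400L)
  expect_false(w$clipped)
  nee2 <- nee; nee2$twist_start <- 10L; nee2$twist_end <- 17L
  nee2$dorsal_start <- 27L; nee2$dorsal_end <- 36L
  nee2$suh_start <- 40L; nee2$suh_end <- 48L
  w2 <- center_window_on_cluster(nee2, rec, 400)
  expect_equal(w2$interval$start, 0L)
  expect_true(w2$clipped)
  expect_error(center_window_on_cluster(nee, rec, 401), "even")
})
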