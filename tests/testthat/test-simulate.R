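test_that("background generation is reproducible and respects composition", {
  r1 <- random_background(500, seed = 1)
  r2 <- random_background(500, seed = 1)
  expect_identical(r1$seq, r2$seq)
  expect_false(identical(r1$seq, random_background(500, seed = 2)$seq))
  expect_equal(random_background(50, composition = c(1, 0, 0, 0),
                                 seed = 3)$seq, strrep("A", 50))
  # frequencies within binomial bounds at length 100k
  big <- random_background(100000, seed = 4)
  freqs <- table(strsplit(big$seq, "")[[1]]) / 100000
  sigma <- sqrt(0.25 * 0.75 / 100000)
  expect_true(all(abs(freqs - 0.25) < 3 * sigma))
  expect_error(random_background(100, composition = c(0.5, 0.5, 0.5, 0.5),
                                 seed = 1), "sum to 1")
})

test_that("first-order Markov backgrounds follow the transition matrix", {
  P <- matrix(0, 4, 4); P[, 1] <- 1 # everything moves to A
  r <- random_background(100, composition = P, seed = 5)
  expect_equal(substr(r$seq, 2, 100), strrep("A", 99))
})

test_that("planted NEEs are recovered with exact spacer and Su(H) position", {
  pn <- plant_nee(600, spacer_len = 8, suh_offset = 60, seed = 42)
  cand <- find_nees(pn$record)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$spacer_len, 8L)
  expect_equal(cand$twist_start, pn$truth$twist_start)
  expect_equal(cand$suh_start, pn$truth$suh_start)
  expect_equal(cand$suh_distance, 60L)
  # same seed, same sequence
  expect_identical(plant_nee(600, 8, 60, seed = 42)$record$seq,
                   pn$record$seq)
  expect_error(plant_nee(300, spacer_len = 8, suh_offset = 280, seed = 1),
               "exceeds")
  expect_error(plant_nee(600, spacer_len = 42, suh_offset = 50, seed = 1),
               "spacer_len")
})

test_that("a Su(H) site just outside the window yields no candidate", {
  pn <- plant_nee(900, spacer_len = 8, suh_offset = 301, seed = 43)
  expect_equal(nrow(find_nees(pn$record)), 0L)
  expect_equal(nrow(find_nees(pn$record, suh_window = 301L)), 1L)
})

test_that("slippage with zero rates is the identity", {
  rec <- random_background(400, seed = 51)
  m <- slippage_model(per_site_rate = 0, point_mut_rate = 0)
  out <- evolve_slippage(rec, m, generations = 50, seed = 1)
  expect_identical(out$seq, rec$seq)
})

test_that("pure expansion never shrinks the sequence and adds MSR", {
  rec <- random_background(400, seed = 52)
  m <- slippage_model(per_site_rate = 0.1, p_expand = 1)
  lens <- rec$length
  cur <- rec
  for (g in 1:10) {
    cur <- evolve_slippage(cur, m, generations = 5, seed = 100 + g)
    lens <- c(lens, cur$length)
  }
  expect_true(all(diff(lens) >= 0))
  expect_gt(cur$length, rec$length)
})

test_that("slippage model arguments are validated", {
  expect_error(slippage_model(p_expand = 1.5))
  expect_error(slippage_model(per_site_rate = -1))
  expect_error(slippage_model(min_copies_seed = 1))
})

test_that("protected motifs survive slippage evolution", {
  pn <- plant_nee(600, spacer_len = 10, suh_offset = 60, seed = 53)
  tr <- pn$truth
  prot <- data.frame(
    start = c(tr$twist_start, tr$dorsal_start, tr$suh_start),
    end = c(tr$twist_start + 7L, tr$dorsal_start + 9L, tr$suh_start + 8L))
  m <- slippage_model(per_site_rate = 0.05, p_expand = 0.6,
                      point_mut_rate = 0.001)
  ev <- evolve_slippage(pn$record, m, generations = 100, seed = 54,
                        protect = prot)
  # sites persist (possibly shifted): one Twist, one Dorsal core, one Su(H)
  expect_gte(nrow(scan_motif(ev, "Twi:Da", "both")), 1L)
  expect_gte(nrow(scan_motif(ev, "Dorsal_core", "both")), 1L)
  expect_gte(nrow(scan_motif(ev, "SuH", "both")), 1L)
  fin <- attr(ev, "protect")
  # protected intervals still delimit the planted instances
  expect_equal(substr(ev$seq, fin$start[1] + 1, fin$end[1]), "CACATGT")
})

test_that("expansion-biased slippage raises windowed MSR content", {
  wins <- 0L
  for (i in 1:10) {
    pn <- plant_nee(600, spacer_len = 10, suh_offset = 60, seed = 60 + i)
    c0 <- msr_content(pn$record, c(100, 500))
    ev <- evolve_slippage(pn$record,
                          slippage_model(per_site_rate = 0.05,
                                         p_expand = 0.6),
                          generations = 100, seed = 160 + i)
    mid <- ev$length %/% 2
    c1 <- msr_content(ev, c(mid - 200, mid + 200))
    wins <- wins + (c1 > c0)
  }
  expect_gte(wins, 8L)
})

test_that("ortholog copies carry the requested divergence", {
  rec <- random_background(600, seed = 55)
  same <- make_ortholog_pair(rec, divergence = 0, indel_rate = 0, seed = 1)
  expect_identical(same$seq, rec$seq)
  div <- make_ortholog_pair(rec, divergence = 0.25, indel_rate = 0, seed = 2)
  h <- align_pair(rec, div, both_strands = FALSE)
  expect_equal(h$identity[1], 0.75, tolerance = 0.05)
  expect_error(make_ortholog_pair(rec, divergence = 0.6, seed = 1))
})

test_that("benchmark sets reproduce their planted partition labels", {
  bench <- make_benchmark_sets(25, 25, msr_effect = 0.2, seed = 56)
  p <- partition_blocks(bench$blocks)
  expect_setequal(p$test_ids, bench$truth$id[bench$truth$set == "test"])
  expect_setequal(p$control_ids,
                  bench$truth$id[bench$truth$set == "control"])
  expect_length(p$dropped_ids, 0L)
  # reproducible
  bench2 <- make_benchmark_sets(25, 25, msr_effect = 0.2, seed = 56)
  expect_identical(bench$blocks$seq, bench2$blocks$seq)
  # planted tracts are detected as CA-dinucleotide presence
  planted <- bench$truth$planted_msr
  pres <- vapply(bench$blocks$seq, msr_class_presence, logical(1),
                 "CA_dinuc", min_copies = 5)
  expect_true(all(pres[planted]))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(random_background(100, seed = 9))
  invisible(make_benchmark_sets(5, 5, 0, seed = 9))
  expect_identical(.Random.seed, before)
})
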