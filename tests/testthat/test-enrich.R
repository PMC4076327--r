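test_that("partition rules route blocks to test, control, or dropped", {
  blocks <- data.frame(
    id = c("zelda_perfect", "zelda_variant", "double_suh", "clean"),
    seq = c(
      paste0(strrep("T", 50), "CAGGTAA", strrep("T", 50)),
      paste0(strrep("T", 50), "CAGGCAA", strrep("T", 50)),
      paste0(strrep("T", 30), "TGTGAGAA", strrep("G", 30), "TGTGAGAA",
             strrep("T", 30)),
      strrep("GAT", 40)),
    stringsAsFactors = FALSE)
  p <- partition_blocks(blocks)
  expect_equal(p$test_ids, "zelda_perfect")
  expect_equal(p$control_ids, "clean")
  expect_setequal(p$dropped_ids, c("zelda_variant", "double_suh"))
  # a true partition: every id in exactly one set
  expect_setequal(c(p$test_ids, p$control_ids, p$dropped_ids), blocks$id)
  expect_length(intersect(p$test_ids, p$control_ids), 0L)
})

test_that("depletion motifs are counted on both strands", {
  blocks <- data.frame(
    id = "minus_zelda",
    # revcomp of CAGGTAA is TTACCTG: a minus-strand perfect Zelda site
    seq = paste0(strrep("G", 50), "TTACCTG", strrep("G", 50)),
    stringsAsFactors = FALSE)
  p <- partition_blocks(blocks)
  expect_equal(p$test_ids, "minus_zelda")
})

test_that("MSR-class presence matches simple constructions", {
  pad <- strrep("GAT", 20)
  expect_true(msr_class_presence(paste0(pad, "CACACACA", pad), "CA_dinuc",
                                 min_copies = 3))
  expect_false(msr_class_presence(paste0(pad, "CACA", pad), "CA_dinuc",
                                  min_copies = 3))
  expect_true(msr_class_presence(paste0(pad, "CAGCAGCAG", pad), "CAR_trinuc",
                                 min_copies = 3))
  expect_true(msr_class_presence(paste0(pad, "AGAGAGAG", pad), "AG_dinuc",
                                 min_copies = 3))
  expect_true(msr_class_presence("GGGTTTTTTGG", "T_run", min_copies = 5))
  expect_false(t_rich_presence("TATATA", min_run = 3))
  expect_true(t_rich_presence("CCTTTTTCC", min_run = 5))
  # minus strand phases count
  expect_true(msr_class_presence(paste0(pad, "TGTGTGTG", pad), "CA_dinuc",
                                 min_copies = 3))
  expect_error(msr_class_presence("ACGT", "CA_dinuc", min_copies = 1),
               "min_copies")
})

test_that("class presence agrees with a tandem-tract oracle on random blocks", {
  set.seed(71)
  units <- list(CA_dinuc = c("CA", "AC", "TG", "GT"),
                AG_dinuc = c("AG", "GA", "CT", "TC"))
  for (i in 1:30) {
    s <- random_dna(600)
    if (i %% 3 == 0) { # plant a tract in a third of the cases
      tract <- strrep(sample(c("CA", "AG"), 1), sample(4:8, 1))
      pos <- sample(1:(600 - nchar(tract)), 1)
      substr(s, pos, pos + nchar(tract) - 1) <- tract
    }
    tr <- find_tandem_repeats(s)
    for (cl in names(units)) {
      oracle <- any(tr$unit_len == 2 & tr$unit_seq %in% units[[cl]] &
                      tr$copies >= 4)
      expect_equal(msr_class_presence(s, cl, min_copies = 4), oracle,
                   info = paste(i, cl))
    }
    # T-run oracle via run-length encoding
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(ch)
    oracle_t <- any(r$lengths >= 5 & r$values %in% c("T", "A"))
    expect_equal(t_rich_presence(s, 5), oracle_t, info = i)
  }
})

test_that("Fisher p equals the hypergeometric oracle on exhaustive small tables", {
  for (n1 in 1:8) {
    for (n2 in 1:8) {
      for (a in 0:n1) {
        for (c in 0:n2) {
          p_impl <- stats::fisher.test(matrix(c(a, n1 - a, c, n2 - c), 2,
                                              byrow = TRUE))$p.value
          p_oracle <- oracle_fisher_p(a, n1 - a, c, n2 - c)
          if (abs(p_impl - p_oracle) > 1e-12) {
            fail(sprintf("mismatch at %d/%d %d/%d", a, n1, c, n2))
          }
        }
      }
    }
  }
  succeed()
})

test_that("enrichment on an all-absent table gives OR 1 and p 1", {
  blocks <- data.frame(
    id = c(sprintf("t%02d", 1:10), sprintf("c%02d", 1:10)),
    seq = c(rep(paste0(strrep("GAT", 20), "CAGGTAA", strrep("GAT", 20)), 10),
            rep(strrep("GTA", 45), 10)),
    stringsAsFactors = FALSE)
  p <- partition_blocks(blocks)
  expect_length(p$test_ids, 10L)
  expect_length(p$control_ids, 10L)
  res <- enrichment_test(p, blocks, "CA_dinuc", min_copies = 5,
                         n_perm = 500, seed = 4)
  expect_equal(unname(res$table), c(0L, 10L, 0L, 10L))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_fisher, 1)
  expect_error(enrichment_test(
    structure(list(test_ids = character(0), control_ids = p$control_ids),
              class = "set_partition"),
    blocks, "CA_dinuc"), "nonempty")
})

test_that("permutation p is reproducible under a fixed seed and tracks Fisher", {
  bench <- make_benchmark_sets(60, 60, msr_effect = 0.45, seed = 21)
  p <- partition_blocks(bench$blocks)
  r1 <- enrichment_test(p, bench$blocks, "CA_dinuc", min_copies = 5,
                        n_perm = 2000, seed = 77)
  r2 <- enrichment_test(p, bench$blocks, "CA_dinuc", min_copies = 5,
                        n_perm = 2000, seed = 77)
  expect_identical(r1$p_perm, r2$p_perm)
  # strong planted effect: both routes reject decisively
  expect_lt(r1$p_fisher, 0.01)
  expect_lt(r1$p_perm, 0.01)
  expect_gt(r1$odds_ratio, 1)
})

test_that("E-value distribution comparison reports shift direction", {
  part <- structure(list(test_ids = sprintf("t%02d", 1:50),
                         control_ids = sprintf("c%02d", 1:50)),
                    class = "set_partition")
  ev_same <- stats::setNames(rep(10^-(1:50), 2),
                             c(part$test_ids, part$control_ids))
  chk <- evalue_distribution_check(part, ev_same)
  expect_equal(chk$auc_test_more_conserved, 0.5)
  ev_shift <- ev_same
  ev_shift[part$test_ids] <- ev_shift[part$test_ids] * 1e-30
  chk2 <- evalue_distribution_check(part, ev_shift)
  expect_gt(chk2$auc_test_more_conserved, 0.5)
  expect_equal(chk2$direction, "test more conserved")
})
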