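test_that("a single anchor with flank 296 gives a 600 bp block", {
  s <- strrep("T", 900)
  s <- paste0(substr(s, 1, 300), "TGTGAGAA", substr(s, 309, 900))
  blocks <- extract_blocks(seq_record("r", s), "SuH", flank = 296)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$start, 4L)
  expect_equal(blocks$end, 604L)
  expect_equal(nchar(blocks$seq), 600L)
  expect_false(blocks$truncated)
  expect_false(blocks$is_cluster)
  expect_equal(blocks$id, "r:4-604")
})

test_that("anchors merge into clusters under the gap threshold", {
  mk <- function(gap) {
    paste0(strrep("T", 600), "TGTGAGAA", strrep("G", gap), "TGTGAGAA",
           strrep("T", 600))
  }
  b1 <- extract_blocks(seq_record("r", mk(100)), "SuH",
                       flank = 270, merge_threshold = 540)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_anchors, 2L)
  expect_true(b1$is_cluster)
  b2 <- extract_blocks(seq_record("r", mk(1000)), "SuH",
                       flank = 270, merge_threshold = 540)
  expect_equal(nrow(b2), 2L)
  expect_true(all(!b2$is_cluster))
  # boundary: gap exactly at the threshold starts a new block
  b3 <- extract_blocks(seq_record("r", mk(540)), "SuH",
                       flank = 270, merge_threshold = 540)
  expect_equal(nrow(b3), 2L)
  b4 <- extract_blocks(seq_record("r", mk(539)), "SuH",
                       flank = 270, merge_threshold = 540)
  expect_equal(nrow(b4), 1L)
})

test_that("blocks near contig edges are kept and flagged truncated", {
  s <- paste0(strrep("T", 50), "TGTGAGAA", strrep("T", 800))
  b <- extract_blocks(seq_record("r", s), "SuH", flank = 296)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 0L)
  expect_true(b$truncated)
})

test_that("block membership equals single-linkage clustering of anchor gaps", {
  genome <- make_synthetic_genome(n_contigs = 4, contig_len = 20000,
                                  seed = 11, n_cluster_pairs = 6,
                                  pair_gap = 100)
  for (mt in c(540L, 592L, 1200L)) {
    blocks <- extract_blocks(genome, "SuH", flank = 296, merge_threshold = mt)
    total_anchors <- sum(count_hits(genome, "SuH")$n_hits)
    expect_equal(sum(blocks$n_anchors), total_anchors)
    for (rec in genome) {
      hits <- scan_motif(rec, "SuH", "both")
      if (nrow(hits) == 0L) next
      gaps <- hits$start[-1] - cummax(hits$end[-nrow(hits)])
      oracle_sizes <- as.integer(table(cumsum(c(1L, gaps >= mt))))
      got <- blocks[blocks$seq_id == rec$id, ]
      expect_equal(got$n_anchors, oracle_sizes, info = paste(rec$id, mt))
    }
  }
})

test_that("raising the merge threshold never increases the block count", {
  genome <- make_synthetic_genome(n_contigs = 3, contig_len = 15000,
                                  seed = 12, n_cluster_pairs = 4)
  counts <- vapply(c(100L, 300L, 540L, 592L, 2000L), function(mt) {
    nrow(extract_blocks(genome, "SuH", flank = 296, merge_threshold = mt))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blocks are disjoint whenever merge_threshold >= 2*flank", {
  genome <- make_synthetic_genome(n_contigs = 3, contig_len = 15000,
                                  seed = 13, n_cluster_pairs = 4)
  blocks <- extract_blocks(genome, "SuH", flank = 296, merge_threshold = 592)
  for (id in unique(blocks$seq_id)) {
    b <- blocks[blocks$seq_id == id, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1L) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("block_stats summarises counts and handles empty input", {
  empty <- extract_blocks(seq_record("r", strrep("A", 100)), "SuH")
  st0 <- block_stats(empty)
  expect_equal(st0$n_blocks, 0L)
  expect_equal(st0$cluster_fraction, 0)
  blocks <- data.frame(is_cluster = c(TRUE, FALSE, FALSE, FALSE),
                       truncated = c(FALSE, TRUE, FALSE, FALSE))
  st <- block_stats(blocks)
  expect_equal(st$n_blocks, 4L)
  expect_equal(st$cluster_fraction, 0.25)
  expect_equal(st$truncated_fraction, 0.25)
})

test_that("Zelda blocks are +/-300 bp around CAGGTAR with 607 bp totals", {
  s <- paste0(strrep("T", 800), "CAGGTAA", strrep("T", 800))
  b <- zelda_blocks(list(seq_record("r", s)))
  expect_equal(nrow(b), 1L)
  expect_equal(nchar(b$seq), 607L)
  expect_equal(b$start, 500L)
  s2 <- paste0(strrep("T", 50), "CAGGTAG", strrep("T", 800))
  b2 <- zelda_blocks(list(seq_record("r", s2)))
  expect_true(b2$truncated)
  expect_equal(b2$start, 0L)
  expect_equal(nrow(zelda_blocks(list(seq_record("r", strrep("T", 500))))), 0L)
})
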