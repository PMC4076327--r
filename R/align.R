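# Word-seeded local alignment for indel-riddled regulatory DNA, with the
# blastn-style scoring scheme used throughout the study's cross-species
# analyses. Each query/subject pair is processed in two stages, on both
# subject strands:
#
#  1. every shared exact `word_size`-mer seeds an ungapped x-drop extension
#     (one extension per diagonal);
#  2. if the best ungapped extension reaches `gapped_trigger`, a full
#     affine-gap local DP (exact Smith-Waterman) is run and the optimal local
#     alignment reported with its traceback.
#
# Running the gapped stage as an exact DP rather than a banded x-drop
# extension makes reported scores equal to the full Smith-Waterman optimum
# whenever a seed exists; `xdrop_final` governs the ungapped stage. E-values
# use ungapped Karlin-Altschul statistics, E = K * m * n * exp(-lambda * S);
# no effective-length (edge) correction is applied by default.

#' Alignment scoring scheme
#'
#' Defaults are the blastn-style parameter set used for regulatory-DNA
#' homology search: reward +5, penalty -4, gap open 8, gap extend 6 (a gap of
#' length L costs `gap_open + L * gap_extend`), word size 9, final x-drop 90,
#' and the best-hit culling parameters (overhang 0.25, score edge 0.1).
#'
#' @param reward Match reward (> 0).
#' @param penalty Mismatch penalty (< 0).
#' @param gap_open,gap_extend Affine gap costs (>= 0).
#' @param word_size Exact-seed length (>= 4).
#' @param xdrop_final X-drop for seed extension.
#' @param best_hit_overhang,best_hit_score_edge Overlap-culling parameters.
#' @param gapped_trigger Minimum best ungapped score that triggers the gapped
#'   stage (default 50).
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(reward = 5L, penalty = -4L, gap_open = 8L,
                           gap_extend = 6L, word_size = 9L,
                           xdrop_final = 90L, best_hit_overhang = 0.25,
                           best_hit_score_edge = 0.1, gapped_trigger = 50L) {
  if (reward <= 0) stop("reward must be > 0")
  if (penalty >= 0) stop("penalty must be < 0")
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be >= 0")
  if (word_size < 4) stop("word_size must be >= 4")
  structure(list(reward = as.integer(reward), penalty = as.integer(penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 xdrop_final = as.integer(xdrop_final),
                 best_hit_overhang = best_hit_overhang,
                 best_hit_score_edge = best_hit_score_edge,
                 gapped_trigger = as.integer(gapped_trigger)),
            class = "scoring_scheme")
}

#' Ungapped Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` solves `sum_ij p_i p_j exp(lambda * s(i,j)) = 1` by bracketed
#' root-finding (tolerance 1e-9). `H` is the relative entropy
#' `lambda * sum_ij p_i p_j s(i,j) exp(lambda * s(i,j))` in nats. `K` is
#' computed by the standard ungapped lattice formula
#' `K = d * lambda * exp(-2*sigma) / (H * (1 - exp(-lambda*d)))`, where `d`
#' is the lattice span of the score support and
#' `sigma = sum_k (1/k) * (P(S_k >= 0) + E[exp(lambda*S_k); S_k < 0])` is
#' accumulated over k-fold convolutions of the score distribution.
#'
#' @param scheme A [scoring_scheme()].
#' @param base_freqs Background base frequencies (A, C, G, T), summing to 1.
#' @return List with `lambda`, `K`, `H`.
#' @export
estimate_karlin <- function(scheme, base_freqs = rep(0.25, 4)) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (abs(sum(base_freqs) - 1) > 1e-8) stop("base_freqs must sum to 1")
  p_match <- sum(base_freqs^2)
  p_mis <- 1 - p_match
  scores <- c(scheme$reward, scheme$penalty)
  probs <- c(p_match, p_mis)
  if (sum(scores * probs) >= 0) {
    stop("invalid scoring scheme: expected score must be negative")
  }
  f <- function(lam) sum(probs * exp(lam * scores)) - 1
  # bracket: f(0)=0 with negative slope; the positive root lies below
  # log(1/p_match)/reward + 1
  hi <- log(1 / p_match) / scheme$reward + 1
  lambda <- stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  H <- lambda * sum(probs * scores * exp(lambda * scores))
  d <- lattice_span(scores)
  sigma <- karlin_sigma(scores, probs, lambda)
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

# Lattice span of the score support: gcd of the attainable score values.
lattice_span <- function(scores) {
  gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)
  d <- 0
  for (s in scores) d <- gcd2(d, abs(s))
  max(d, 1)
}

# sigma = sum_{k>=1} (1/k) [ P(S_k >= 0) + E(e^{lambda S_k}; S_k < 0) ] over
# k-fold convolutions of the per-position score distribution; the summand
# decays geometrically, so a modest iteration cap suffices.
karlin_sigma <- function(scores, probs, lambda, iter = 60L) {
  lo <- min(scores); hi <- max(scores)
  # distribution of S_k on support [k*lo, k*hi], index offset
  dist <- numeric(hi - lo + 1)
  dist[scores - lo + 1] <- probs
  cur <- dist; cur_lo <- lo
  step <- dist
  sigma <- 0
  for (k in seq_len(iter)) {
    if (k > 1) {
      cur <- convolve_shift(cur, step)
      cur_lo <- cur_lo + lo
    }
    vals <- seq(cur_lo, by = 1, length.out = length(cur))
    neg <- vals < 0
    term <- sum(cur[!neg]) + sum(cur[neg] * exp(lambda * vals[neg]))
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
  }
  sigma
}

convolve_shift <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(b)) {
    if (b[i] != 0) {
      idx <- seq_along(a) + i - 1L
      out[idx] <- out[idx] + a * b[i]
    }
  }
  out
}

#' E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`; strictly decreasing in `S` for fixed
#' sequence lengths.
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject lengths in bp.
#' @param karlin Karlin-Altschul parameters from [estimate_karlin()].
#' @return Positive E-value.
#' @export
karlin_evalue <- function(score, m, n, karlin) {
  karlin$K * as.numeric(m) * as.numeric(n) * exp(-karlin$lambda * score)
}

#' Align a query/subject pair
#'
#' Seeded two-stage alignment (see the module description above). Both
#' subject strands are searched; hits are reported on plus-strand subject
#' coordinates with `strand` recording the orientation, then culled by the
#' best-hit overhang/score-edge rule.
#'
#' @param query,subject `seq_record` objects (or plain DNA strings).
#' @param scheme A [scoring_scheme()].
#' @param karlin Precomputed [estimate_karlin()] output (uniform base
#'   frequencies assumed when omitted).
#' @param both_strands Also align against the reverse complement of the
#'   subject (default `TRUE`).
#' @return Data frame of hits: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `score`, `evalue`, `identity`, `edit`.
#' @export
align_pair <- function(query, subject, scheme = scoring_scheme(),
                       karlin = NULL, both_strands = TRUE) {
  if (is.character(query)) query <- seq_record("query", query)
  if (is.character(subject)) subject <- seq_record("subject", subject)
  if (is.null(karlin)) karlin <- estimate_karlin(scheme)
  hits <- list()
  if (query$length >= scheme$word_size && subject$length >= scheme$word_size) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      s_seq <- if (strand == "+") subject$seq else revcomp(subject$seq)
      ug <- cpp_best_ungapped(query$seq, s_seq, scheme$word_size,
                              scheme$reward, scheme$penalty,
                              scheme$xdrop_final)
      if (ug$score < scheme$gapped_trigger) next
      sw <- cpp_sw_affine(query$seq, s_seq, scheme$reward, scheme$penalty,
                          scheme$gap_open, scheme$gap_extend)
      if (sw$score <= 0) next
      ops <- strsplit(sw$edit, "", fixed = TRUE)[[1]]
      s_start <- sw$s_start; s_end <- sw$s_end
      if (strand == "-") {
        s_start <- subject$length - sw$s_end
        s_end <- subject$length - sw$s_start
      }
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = query$id, subject_id = subject$id,
        q_start = sw$q_start, q_end = sw$q_end,
        s_start = s_start, s_end = s_end, strand = strand,
        score = sw$score,
        evalue = karlin_evalue(sw$score, query$length, subject$length, karlin),
        identity = sum(ops == "=") / length(ops),
        edit = sw$edit, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty_alignment_hits()
  cull_best_hits(out, scheme)
}

empty_alignment_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), strand = character(0), score = integer(0),
             evalue = numeric(0), identity = numeric(0), edit = character(0),
             stringsAsFactors = FALSE)
}

# Best-hit culling: hit B is removed when a stronger kept hit A exists whose
# query interval, extended by best_hit_overhang * length(B) on each side,
# contains B, and score(B) < (1 - best_hit_score_edge) * score(A).
cull_best_hits <- function(hits, scheme) {
  if (nrow(hits) <= 1L) return(hits)
  hits <- hits[order(-hits$score, hits$subject_id, hits$s_start), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (b in seq_len(nrow(hits))[-1]) {
    len_b <- hits$q_end[b] - hits$q_start[b]
    over <- scheme$best_hit_overhang * len_b
    for (a in which(keep[seq_len(b - 1L)])) {
      contained <- hits$q_start[b] >= hits$q_start[a] - over &&
        hits$q_end[b] <= hits$q_end[a] + over
      weaker <- hits$score[b] <
        (1 - scheme$best_hit_score_edge) * hits$score[a]
      if (contained && weaker) { keep[b] <- FALSE; break }
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescore an alignment edit string
#'
#' Recomputes the raw score of a hit from its edit string (`=` match, `X`
#' mismatch, `D` gap in subject, `I` gap in query) under a scoring scheme;
#' reported scores always reproduce exactly.
#'
#' @param edit Edit string.
#' @param scheme A [scoring_scheme()].
#' @return Integer score.
#' @export
rescore_edit <- function(edit, scheme = scoring_scheme()) {
  ops <- strsplit(edit, "", fixed = TRUE)[[1]]
  score <- sum(ops == "=") * scheme$reward + sum(ops == "X") * scheme$penalty
  r <- rle(ops)
  gaps <- r$lengths[r$values %in% c("I", "D")]
  score - sum(scheme$gap_open + gaps * scheme$gap_extend)
}

#' All-vs-all block alignment
#'
#' Aligns every block in `blocks_a` against every block in `blocks_b`,
#' keeping the best hit per pair with `evalue < evalue_max`.
#'
#' @param blocks_a,blocks_b Block data frames (columns `id`, `seq`), e.g.
#'   from [extract_blocks()].
#' @param scheme A [scoring_scheme()].
#' @param evalue_max E-value cutoff (default `1e-15`).
#' @param karlin Optional precomputed Karlin-Altschul parameters.
#' @return Alignment-hit data frame (one row per retained pair).
#' @export
all_vs_all <- function(blocks_a, blocks_b, scheme = scoring_scheme(),
                       evalue_max = 1e-15, karlin = NULL) {
  if (is.null(karlin)) karlin <- estimate_karlin(scheme)
  hits <- list()
  recs_a <- lapply(seq_len(nrow(blocks_a)), function(i) {
    seq_record(blocks_a$id[i], blocks_a$seq[i])
  })
  recs_b <- lapply(seq_len(nrow(blocks_b)), function(i) {
    seq_record(blocks_b$id[i], blocks_b$seq[i])
  })
  for (ra in recs_a) {
    for (rb in recs_b) {
      h <- align_pair(ra, rb, scheme, karlin)
      if (nrow(h) == 0L) next
      h <- h[1L, , drop = FALSE] # best after culling
      if (h$evalue < evalue_max) hits[[length(hits) + 1L]] <- h
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty_alignment_hits()
  rownames(out) <- NULL
  out
}

# Best partner per query id under deterministic tie-breaking
# (score desc, then subject_id, then s_start).
best_partner <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$query_id, -hits$score, hits$subject_id,
                     hits$s_start), , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
             stringsAsFactors = FALSE)
}

#' Reciprocal best-hit homologs
#'
#' A pair `(a, b)` is retained iff `b` is `a`'s best partner in `hits_ab`
#' and `a` is `b`'s best partner in `hits_ba`.
#'
#' @param hits_ab Hits of A-blocks queried against B-blocks.
#' @param hits_ba Hits of B-blocks queried against A-blocks.
#' @return Data frame `id_a`, `id_b` of reciprocal pairs.
#' @export
reciprocal_homologs <- function(hits_ab, hits_ba) {
  ab <- best_partner(hits_ab)
  ba <- best_partner(hits_ba)
  names(ab) <- c("id_a", "id_b")
  names(ba) <- c("id_b", "id_a")
  out <- merge(ab, ba, by = c("id_a", "id_b"))
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits in 12-column tabular format
#'
#' Columns mirror the conventional tab-separated alignment summary: query,
#' subject, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end (1-based, inclusive), E-value, score.
#'
#' @param hits Alignment-hit data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  ops <- strsplit(hits$edit, "", fixed = TRUE)
  tab <- data.frame(
    query = hits$query_id, subject = hits$subject_id,
    pident = round(hits$identity * 100, 2),
    length = vapply(ops, length, integer(1)),
    mismatch = vapply(ops, function(o) sum(o == "X"), integer(1)),
    gapopen = vapply(ops, function(o) {
      r <- rle(o); sum(r$values %in% c("I", "D"))
    }, integer(1)),
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = hits$evalue, score = hits$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
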