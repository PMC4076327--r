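# Partition of conserved blocks into an embryonic (Zelda-positive) test set
# and a depleted control set, plus presence/absence enrichment of
# pre-specified MSR classes between the two. De novo EM motif discovery is
# out of scope: the study's conclusions concern specific repeat families
# ((CA)n, (CAR)n, (AG)n, T-runs), which are tested directly.

#' Partition blocks into Zelda-positive test and depleted control sets
#'
#' Test set: blocks with at least one perfect Zelda site (`CAGGTAR`, both
#' strands). Control set: blocks with zero hits to any depletion motif
#' (`CAGGTA`, `CAGGCAR`, `TAGGTAR`) and at most `max_suh_in_control` relaxed
#' Su(H) hits (`GTGNGAA`). Blocks in neither set are tracked as dropped (a
#' perfect-Zelda block also matches `CAGGTA`, so test and control are
#' disjoint by construction).
#'
#' @param blocks Block data frame (columns `id`, `seq`).
#' @param zelda_positive Test-set motif (default `CAGGTAR`).
#' @param depletion_motifs Control-set exclusion motifs.
#' @param suh_relaxed Relaxed Su(H) motif for control depletion.
#' @param max_suh_in_control Maximum relaxed Su(H) hits allowed in control.
#' @return List of class `set_partition`: `test_ids`, `control_ids`,
#'   `dropped_ids`, `criteria`.
#' @export
partition_blocks <- function(blocks, zelda_positive = "CAGGTAR",
                             depletion_motifs = c("CAGGTA", "CAGGCAR",
                                                  "TAGGTAR"),
                             suh_relaxed = "GTGNGAA",
                             max_suh_in_control = 1L) {
  n <- nrow(blocks)
  in_test <- logical(n); in_control <- logical(n)
  for (i in seq_len(n)) {
    rec <- seq_record(blocks$id[i], blocks$seq[i])
    if (nrow(scan_motif(rec, zelda_positive, "both")) > 0L) {
      in_test[i] <- TRUE
      next
    }
    n_depl <- sum(vapply(depletion_motifs, function(m) {
      nrow(scan_motif(rec, m, "both"))
    }, integer(1)))
    n_suh <- nrow(scan_motif(rec, suh_relaxed, "both"))
    in_control[i] <- n_depl == 0L && n_suh <= max_suh_in_control
  }
  structure(list(
    test_ids = blocks$id[in_test],
    control_ids = blocks$id[in_control],
    dropped_ids = blocks$id[!in_test & !in_control],
    criteria = list(zelda_positive = zelda_positive,
                    depletion_motifs = depletion_motifs,
                    suh_relaxed = suh_relaxed,
                    max_suh_in_control = max_suh_in_control)
  ), class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf("<set_partition> test %d | control %d | dropped %d\n",
              length(x$test_ids), length(x$control_ids),
              length(x$dropped_ids)))
  invisible(x)
}

# MSR class definitions: tandem unit families on either strand, listed with
# all phase rotations so a tract is detected regardless of the phase in which
# it is embedded (e.g. (AC)n counts as a CA-dinucleotide repeat).
.MSR_CLASS_UNITS <- list(
  CA_dinuc = c("CA", "AC", "TG", "GT"),
  CAR_trinuc = c("CAA", "AAC", "ACA", "CAG", "AGC", "GCA",
                 "TTG", "TGT", "GTT", "CTG", "TGC", "GCT"),
  AG_dinuc = c("AG", "GA", "CT", "TC"),
  T_run = c("T", "A")
)

#' MSR-class presence in a block
#'
#' `TRUE` iff the block sequence contains at least `min_copies` perfect
#' head-to-tail copies of any unit in the class: `CA_dinuc` (CA/TG),
#' `CAR_trinuc` (CAA/CAG and strand complements), `AG_dinuc` (AG/CT), or
#' `T_run` (a mononucleotide T or A run, where `min_copies` is the minimum
#' run length).
#'
#' @param block One block row (data frame with `seq`) or a DNA string.
#' @param msr_class One of `"CA_dinuc"`, `"CAR_trinuc"`, `"AG_dinuc"`,
#'   `"T_run"`.
#' @param min_copies Minimum tandem copy number (>= 2; for `T_run`, minimum
#'   run length, default 5).
#' @return Logical.
#' @export
msr_class_presence <- function(block, msr_class, min_copies = NULL) {
  seq <- if (is.data.frame(block)) block$seq[1] else block
  msr_class <- match.arg(msr_class, names(.MSR_CLASS_UNITS))
  if (is.null(min_copies)) min_copies <- if (msr_class == "T_run") 5L else 3L
  if (msr_class == "T_run") {
    if (min_copies < 3) stop("min_run must be >= 3")
    return(t_rich_presence(seq, min_run = min_copies))
  }
  if (min_copies < 2) stop("min_copies must be >= 2")
  units <- .MSR_CLASS_UNITS[[msr_class]]
  any(vapply(units, function(u) {
    grepl(sprintf("(?:%s){%d,}", u, min_copies), seq, perl = TRUE)
  }, logical(1)))
}

#' T-rich run presence
#'
#' `TRUE` iff a run of at least `min_run` consecutive `T` (or, on the minus
#' strand, `A`) exists.
#'
#' @param block One block row or a DNA string.
#' @param min_run Minimum run length (>= 3, default 5).
#' @return Logical.
#' @export
t_rich_presence <- function(block, min_run = 5L) {
  seq <- if (is.data.frame(block)) block$seq[1] else block
  if (min_run < 3) stop("min_run must be >= 3")
  grepl(sprintf("T{%d,}|A{%d,}", min_run, min_run), seq, perl = TRUE)
}

#' MSR-class enrichment between test and control blocks
#'
#' Builds the 2x2 presence table (test-with, test-without, control-with,
#' control-without), computes the two-sided Fisher exact p-value, a seeded
#' permutation p-value from `n_perm` random relabelings preserving set sizes,
#' and the odds ratio (with a Haldane 0.5 correction when a zero cell
#' occurs).
#'
#' @param partition A `set_partition` from [partition_blocks()].
#' @param blocks Block data frame carrying `id` and `seq`.
#' @param msr_class MSR class name (see [msr_class_presence()]).
#' @param min_copies Minimum copies/run length for presence.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation stream (recorded in the result).
#' @return List of class `enrichment_result`: `msr_class`, `table`
#'   (a, b, c, d), `odds_ratio`, `p_fisher`, `p_perm`, `n_perm`, `seed`.
#' @export
enrichment_test <- function(partition, blocks, msr_class,
                            min_copies = NULL, n_perm = 10000L, seed = 1L) {
  test_idx <- match(partition$test_ids, blocks$id)
  ctrl_idx <- match(partition$control_ids, blocks$id)
  if (length(test_idx) == 0L || length(ctrl_idx) == 0L) {
    stop("both test and control sets must be nonempty")
  }
  pres <- function(idx) {
    vapply(idx, function(i) {
      msr_class_presence(blocks$seq[i], msr_class, min_copies)
    }, logical(1))
  }
  pt <- pres(test_idx); pc <- pres(ctrl_idx)
  a <- sum(pt); b <- sum(!pt); c <- sum(pc); d <- sum(!pc)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("test", "control"), c("with", "without")))
  p_fisher <- stats::fisher.test(tab)$p.value
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  labels <- c(pt, pc)
  n_test <- length(pt)
  obs_dev <- abs(a - sum(labels) * n_test / length(labels))
  p_perm <- with_seed(seed, {
    dev <- replicate(n_perm, {
      perm <- sample(labels)
      abs(sum(perm[seq_len(n_test)]) -
            sum(labels) * n_test / length(labels))
    })
    (sum(dev >= obs_dev - 1e-9) + 1) / (n_perm + 1)
  })
  structure(list(msr_class = msr_class,
                 table = c(a = a, b = b, c = c, d = d),
                 odds_ratio = or, p_fisher = p_fisher, p_perm = p_perm,
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment %s> test %d/%d vs control %d/%d | OR %.3g | Fisher p %.3g | perm p %.3g\n",
    x$msr_class, x$table["a"], x$table["a"] + x$table["b"],
    x$table["c"], x$table["c"] + x$table["d"],
    x$odds_ratio, x$p_fisher, x$p_perm))
  invisible(x)
}

#' Compare conservation E-value distributions of test and control blocks
#'
#' Rank-based two-sample comparison (Wilcoxon) of log10 E-values, reporting
#' the common-language AUC statistic (probability that a random test block is
#' more conserved, i.e. has a smaller E-value, than a random control block;
#' 0.5 under identical distributions) plus log10-binned histograms.
#'
#' @param partition A `set_partition`.
#' @param evalues Named numeric vector of per-block conservation E-values
#'   (names are block ids).
#' @return List: `auc_test_more_conserved`, `p_wilcox`, `direction`,
#'   `histogram` (data frame of counts per log10 bin and set).
#' @export
evalue_distribution_check <- function(partition, evalues) {
  ev_t <- evalues[partition$test_ids]
  ev_c <- evalues[partition$control_ids]
  ev_t <- ev_t[is.finite(ev_t)]; ev_c <- ev_c[is.finite(ev_c)]
  if (length(ev_t) == 0L || length(ev_c) == 0L) {
    stop("both sets need E-values")
  }
  lt <- log10(ev_t); lc <- log10(ev_c)
  w <- stats::wilcox.test(lt, lc, exact = FALSE)
  auc <- mean(outer(lt, lc, "<") + 0.5 * outer(lt, lc, "=="))
  brk <- pretty(c(lt, lc), n = 20)
  hist_df <- rbind(
    data.frame(set = "test",
               bin = levels(cut(lt, brk))[table(cut(lt, brk)) >= 0],
               count = as.integer(table(cut(lt, brk)))),
    data.frame(set = "control",
               bin = levels(cut(lc, brk))[table(cut(lc, brk)) >= 0],
               count = as.integer(table(cut(lc, brk))))
  )
  list(auc_test_more_conserved = auc,
       p_wilcox = w$p.value,
       direction = if (auc > 0.5) "test more conserved"
                   else if (auc < 0.5) "test less conserved"
                   else "no shift",
       histogram = hist_df)
}
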