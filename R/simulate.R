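# Synthetic-data generators. Every stage of the pipeline is exercised on
# sequences produced here, with known ground truth: i.i.d. or first-order
# Markov background DNA, planted NEE grammars, anchor-site genomes,
# replication-slippage MSR evolution, diverged ortholog pairs, and
# Zelda-positive vs depleted benchmark block sets. All generators are pure
# functions of (parameters, seed); the caller's RNG stream is never touched.

.BASES <- c("A", "C", "G", "T")

#' Random background sequence
#'
#' I.i.d. bases from `composition` (length-4 vector, A/C/G/T order), or a
#' first-order Markov chain when `composition` is a 4x4 transition matrix
#' (rows = current base, initial base from the uniform distribution).
#'
#' @param length Sequence length in bp.
#' @param composition Length-4 frequency vector summing to 1, or 4x4
#'   row-stochastic matrix.
#' @param seed Mandatory integer seed.
#' @param id Record id.
#' @return A `seq_record`.
#' @export
random_background <- function(length, composition = rep(0.25, 4), seed,
                              id = "background") {
  with_seed(seed, {
    seq_record(id, paste(random_bases(length, composition), collapse = ""))
  })
}

# bare generator used inside an existing seeded stream
random_bases <- function(length, composition = rep(0.25, 4)) {
  if (is.matrix(composition)) {
    stopifnot(all(dim(composition) == c(4, 4)),
              all(abs(rowSums(composition) - 1) < 1e-8))
    out <- character(length)
    cur <- sample.int(4L, 1L)
    out[1] <- .BASES[cur]
    for (i in seq_len(length - 1L)) {
      cur <- sample.int(4L, 1L, prob = composition[cur, ])
      out[i + 1L] <- .BASES[cur]
    }
    out
  } else {
    if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
    sample(.BASES, length, replace = TRUE, prob = composition)
  }
}

# One concrete instantiation of an IUPAC motif (uniform over expansions).
instantiate_iupac <- function(iupac) {
  ch <- strsplit(validate_iupac(iupac), "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) {
    cls <- gsub("\\[|\\]", "", .IUPAC_CLASS[[c]])
    opts <- strsplit(cls, "", fixed = TRUE)[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

overwrite_at <- function(seq, pos, insert) {
  # pos is 0-based; returns seq with substring replaced
  substr(seq, pos + 1L, pos + nchar(insert)) <- insert
  seq
}

# Background screened to contain no match (both strands) to any of `motifs`.
clean_background <- function(length, composition, motifs, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    s <- paste(random_bases(length, composition), collapse = "")
    rec <- seq_record("bg", s)
    hit <- any(vapply(motifs, function(m) {
      nrow(scan_motif(rec, m, "both")) > 0L
    }, logical(1)))
    if (!hit) return(s)
  }
  stop("could not generate motif-free background")
}

.GRAMMAR_MOTIFS <- c("SuH", "Twi:Da", "Dorsal_core", "SMMSE")

#' Plant an NEE grammar in background sequence
#'
#' Builds a sequence with a Twist:Da site (`CACATGT`), a spacer of exactly
#' `spacer_len` bp, a Dorsal-core instance, and a Su(H) instance whose
#' nearest edge lies `suh_offset` bp from the pair span (positive = right,
#' negative = left). The background is screened to be free of accidental
#' grammar motifs, so the planted architecture is the only one present.
#'
#' @param length Total sequence length (default 600).
#' @param spacer_len Spacer in bp, 0-41.
#' @param suh_offset Signed Su(H) gap in bp, `abs(suh_offset)` within the
#'   sequence.
#' @param seed Mandatory integer seed.
#' @param id Record id.
#' @param composition Background base frequencies.
#' @param suh_strand Strand of the planted Su(H) instance.
#' @return List: `record` (`seq_record`) and `truth` (planted 0-based
#'   coordinates: `twist_start`, `dorsal_start`, `spacer_len`, `suh_start`,
#'   `suh_strand`).
#' @export
plant_nee <- function(length = 600L, spacer_len, suh_offset, seed,
                      id = "nee", composition = rep(0.25, 4),
                      suh_strand = "+") {
  if (spacer_len < 0L || spacer_len > 41L) stop("spacer_len must be in 0..41")
  with_seed(seed, {
    twist <- "CACATGT"
    dorsal <- instantiate_iupac("GGAAABYCC")
    suh <- instantiate_iupac("YGTGRGAA")
    if (suh_strand == "-") suh <- revcomp(suh)
    pair_len <- 7L + spacer_len + 9L
    pair_start <- (length - pair_len) %/% 2L
    suh_start <- if (suh_offset >= 0) {
      pair_start + pair_len + suh_offset
    } else {
      pair_start + suh_offset - 8L
    }
    if (suh_start < 0L || suh_start + 8L > length) {
      stop("Su(H) placement exceeds the sequence")
    }
    for (try in seq_len(200L)) {
      bg <- clean_background(length, composition, .GRAMMAR_MOTIFS)
      s <- overwrite_at(bg, pair_start, twist)
      s <- overwrite_at(s, pair_start + 7L + spacer_len, dorsal)
      s <- overwrite_at(s, suh_start, suh)
      rec <- seq_record(id, s)
      # the junctions of the planted instances can create extra motif
      # matches; resample until the planted architecture is the only one
      pairs <- find_linked_pairs(rec)
      if (!(nrow(pairs) == 1L && pairs$twist_start == pair_start &&
              pairs$spacer_len == spacer_len)) next
      if (nrow(scan_motif(rec, "SuH", "both")) != 1L) next
      return(list(record = rec,
                  truth = list(twist_start = pair_start,
                               dorsal_start = pair_start + 7L + spacer_len,
                               spacer_len = spacer_len,
                               suh_start = suh_start,
                               suh_strand = suh_strand)))
    }
    stop("could not plant a clean NEE grammar")
  })
}

#' Replication-slippage model parameters
#'
#' Slippage events hit existing tandem tracts; the per-generation expected
#' event count is `per_site_rate` per tract, a tract is chosen with
#' probability proportional to `copies^length_exponent` (instability grows
#' with repeat length), and an event adds one whole unit copy with
#' probability `p_expand` (otherwise removes one). Point substitutions are
#' applied outside protected intervals at `point_mut_rate` per bp per
#' generation.
#'
#' @param per_site_rate Events per tract per generation (>= 0).
#' @param length_exponent Exponent of the copies-dependent event probability.
#' @param p_expand Probability an event expands rather than contracts.
#' @param min_copies_seed Minimum copies for a tract to be slippage-active.
#' @param point_mut_rate Substitutions per bp per generation.
#' @return List of class `slippage_model`.
#' @export
slippage_model <- function(per_site_rate = 0.05, length_exponent = 1,
                           p_expand = 0.6, min_copies_seed = 2L,
                           point_mut_rate = 0) {
  stopifnot(per_site_rate >= 0, length_exponent >= 0,
            p_expand >= 0, p_expand <= 1, min_copies_seed >= 2,
            point_mut_rate >= 0)
  structure(list(per_site_rate = per_site_rate,
                 length_exponent = length_exponent,
                 p_expand = p_expand,
                 min_copies_seed = as.integer(min_copies_seed),
                 point_mut_rate = point_mut_rate),
            class = "slippage_model")
}

#' Evolve a sequence under replication slippage
#'
#' Per generation, tandem tracts (units 2-50 bp, at least
#' `min_copies_seed` copies) gain or lose whole unit copies according to the
#' model; events falling inside protected intervals are suppressed, and
#' point mutations avoid them, emulating binding sites that persist while
#' MSR fills the spacers. Protected intervals are shifted along with the
#' indels they survive.
#'
#' @param record A `seq_record`.
#' @param model A [slippage_model()].
#' @param generations Number of generations (>= 0).
#' @param seed Mandatory integer seed.
#' @param protect Optional data frame of 0-based half-open intervals
#'   (`start`, `end`) to protect.
#' @return The evolved `seq_record`; final protected intervals in
#'   `attr(x, "protect")`.
#' @export
evolve_slippage <- function(record, model, generations, seed,
                            protect = NULL) {
  stopifnot(inherits(record, "seq_record"), inherits(model, "slippage_model"),
            generations >= 0)
  prot <- if (is.null(protect)) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    protect[, c("start", "end")]
  }
  s <- record$seq
  with_seed(seed, {
    for (g in seq_len(generations)) {
      if (model$per_site_rate > 0) {
        tracts <- find_tandem_repeats(seq_record(record$id, s))
        tracts <- tracts[tracts$copies >= model$min_copies_seed, ,
                         drop = FALSE]
        tracts <- primitive_tracts(tracts)
        if (nrow(tracts) > 0L) {
          n_events <- stats::rpois(1L, model$per_site_rate * nrow(tracts))
          n_events <- min(n_events, nrow(tracts))
          if (n_events > 0L) {
            w <- tracts$copies^model$length_exponent
            chosen <- sample.int(nrow(tracts), n_events, prob = w)
            # apply right-to-left so earlier coordinates stay valid
            chosen <- chosen[order(-tracts$start[chosen])]
            for (k in chosen) {
              pos <- tracts$start[k]; u <- tracts$unit_len[k]
              if (in_protected(pos, pos + u, prot)) next
              if (stats::runif(1) < model$p_expand) {
                unit <- substr(s, pos + 1L, pos + u)
                s <- paste0(substr(s, 1L, pos), unit,
                            substr(s, pos + 1L, nchar(s)))
                prot <- shift_intervals(prot, pos, u)
              } else if (tracts$copies[k] > model$min_copies_seed) {
                # a contraction at the minimum copy number would destroy the
                # repeat locus entirely; such events are aborted so tracts
                # contract down to, but not through, the seeding threshold
                s <- paste0(substr(s, 1L, pos),
                            substr(s, pos + u + 1L, nchar(s)))
                prot <- shift_intervals(prot, pos, -u)
              }
            }
          }
        }
      }
      if (model$point_mut_rate > 0) {
        L <- nchar(s)
        n_mut <- stats::rbinom(1L, L, model$point_mut_rate)
        if (n_mut > 0L) {
          cand <- sample.int(L, n_mut) - 1L # 0-based
          cand <- cand[!vapply(cand, function(p) {
            in_protected(p, p + 1L, prot)
          }, logical(1))]
          for (p in cand) {
            old <- substr(s, p + 1L, p + 1L)
            s <- overwrite_at(s, p, sample(setdiff(.BASES, old), 1L))
          }
        }
      }
    }
    out <- seq_record(record$id, s, description = record$description,
                      species = record$species)
    attr(out, "protect") <- prot
    out
  })
}

# One slippage-active tract per repeat locus: drop tracts whose unit is
# itself a repetition of a shorter unit (a (CA)10 run is one CA locus, not
# additionally a CACA / CACACA locus), then collapse overlapping same-unit
# phase rotations to the leftmost one. Without this, the event count per
# locus would scale with the number of redundant detector reports rather
# than with the number of repeat loci.
primitive_tracts <- function(tracts) {
  if (nrow(tracts) == 0L) return(tracts)
  is_primitive <- vapply(seq_len(nrow(tracts)), function(i) {
    u <- tracts$unit_len[i]; unit <- tracts$unit_seq[i]
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L && strrep(substr(unit, 1L, d), u %/% d) == unit) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  tracts <- tracts[is_primitive, , drop = FALSE]
  keep <- rep(TRUE, nrow(tracts))
  for (i in seq_len(nrow(tracts))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    same <- prev[tracts$unit_len[prev] == tracts$unit_len[i] &
                   tracts$end[prev] > tracts$start[i]]
    if (length(same)) keep[i] <- FALSE
  }
  out <- tracts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

in_protected <- function(start, end, prot) {
  any(prot$start < end & start < prot$end)
}

shift_intervals <- function(prot, pos, delta) {
  # indel of signed length delta at 0-based position pos (insertion before
  # pos+1 / deletion of [pos, pos-delta))
  prot$start <- ifelse(prot$start > pos, prot$start + delta, prot$start)
  prot$end <- ifelse(prot$end > pos, prot$end + delta, prot$end)
  prot$end <- pmax(prot$end, prot$start)
  prot
}

#' Diverged ortholog copy of a sequence
#'
#' Each position is substituted with probability `divergence` (to a uniformly
#' chosen different base); short indels (1-3 bp, insertion or deletion with
#' equal probability) occur at `indel_rate` expected events per bp.
#'
#' @param record A `seq_record`.
#' @param divergence Substitution probability per bp, in `[0, 0.5)`.
#' @param indel_rate Expected indel events per bp.
#' @param seed Mandatory integer seed.
#' @param id Id of the copy (default `<id>_ortholog`).
#' @return A `seq_record`.
#' @export
make_ortholog_pair <- function(record, divergence, indel_rate = 0, seed,
                               id = paste0(record$id, "_ortholog")) {
  stopifnot(divergence >= 0, divergence < 0.5, indel_rate >= 0)
  with_seed(seed, {
    ch <- strsplit(record$seq, "", fixed = TRUE)[[1]]
    mut <- which(stats::runif(length(ch)) < divergence)
    for (i in mut) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
    s <- paste(ch, collapse = "")
    n_indel <- stats::rpois(1L, indel_rate * nchar(s))
    for (k in seq_len(n_indel)) {
      L <- nchar(s)
      pos <- sample.int(L, 1L)
      len <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {
        ins <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
        s <- paste0(substr(s, 1L, pos), ins, substr(s, pos + 1L, L))
      } else if (pos + len <= L) {
        s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + len, L))
      }
    }
    seq_record(id, s, species = record$species)
  })
}

#' Synthetic multi-contig genome
#'
#' Plain i.i.d. background contigs; anchor motifs (e.g. Su(H)) occur at their
#' chance frequency, so block extraction, clustering and truncation
#' bookkeeping can be exercised at genome scale. Optionally plants
#' `n_cluster_pairs` pairs of Su(H) instances at a fixed within-pair gap to
#' guarantee clustered anchors.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp.
#' @param seed Mandatory integer seed.
#' @param composition Base frequencies.
#' @param n_cluster_pairs Planted Su(H) site pairs (default 0).
#' @param pair_gap Gap between planted pair members in bp (default 100).
#' @return List of `seq_record` contigs.
#' @export
make_synthetic_genome <- function(n_contigs = 20L, contig_len = 20000L, seed,
                                  composition = rep(0.25, 4),
                                  n_cluster_pairs = 0L, pair_gap = 100L) {
  with_seed(seed, {
    contigs <- lapply(seq_len(n_contigs), function(i) {
      seq_record(sprintf("contig%02d", i),
                 paste(random_bases(contig_len, composition), collapse = ""))
    })
    for (k in seq_len(n_cluster_pairs)) {
      ci <- ((k - 1L) %% n_contigs) + 1L
      pos <- sample.int(contig_len - pair_gap - 200L, 1L) + 50L
      site1 <- instantiate_iupac("YGTGRGAA")
      site2 <- instantiate_iupac("YGTGRGAA")
      s <- contigs[[ci]]$seq
      s <- overwrite_at(s, pos, site1)
      s <- overwrite_at(s, pos + 8L + pair_gap, site2)
      contigs[[ci]] <- seq_record(contigs[[ci]]$id, s)
    }
    contigs
  })
}

#' Benchmark block sets with a planted MSR presence effect
#'
#' Emulates the embryonic-vs-control design: `n_test` blocks each carry one
#' perfect Zelda site and `n_control` blocks are screened to carry no
#' Zelda-like site and at most one relaxed Su(H) site, so
#' [partition_blocks()] reproduces the planted labels exactly. A
#' slippage-style CA tract (copy number 6-12) is planted with probability
#' `base_presence` in control blocks and `base_presence + msr_effect` in test
#' blocks.
#'
#' @param n_test,n_control Set sizes (> 0).
#' @param msr_effect Additive effect on CA-tract presence probability.
#' @param seed Mandatory integer seed.
#' @param block_len Block length in bp (default 600).
#' @param base_presence Baseline planted-tract probability (default 0.15,
#'   keeping presence rates low enough that a +0.2 effect is a strong,
#'   well-powered contrast at the benchmark set sizes).
#' @return List: `blocks` (data frame `id`, `seq`), `truth` (data frame
#'   `id`, `set`, `planted_msr`).
#' @export
make_benchmark_sets <- function(n_test, n_control, msr_effect, seed,
                                block_len = 600L, base_presence = 0.15) {
  stopifnot(n_test > 0, n_control > 0,
            base_presence + msr_effect >= 0, base_presence + msr_effect <= 1)
  depletion <- c("CAGGTA", "CAGGCAR", "TAGGTAR")
  with_seed(seed, {
    gen_batch <- function(n) {
      m <- matrix(sample(.BASES, n * block_len, replace = TRUE), nrow = n)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    plant_ca <- function(s, avoid_start = NA, avoid_end = NA) {
      copies <- sample(6:12, 1L)
      tract <- strrep("CA", copies)
      repeat {
        pos <- sample.int(nchar(s) - nchar(tract), 1L)
        if (is.na(avoid_start) ||
            pos >= avoid_end || pos + nchar(tract) <= avoid_start) break
      }
      overwrite_at(s, pos, tract)
    }
    # violates the control criteria: any depletion-motif hit (both strands)
    # or more than one relaxed Su(H) hit
    control_bad <- function(seqs) {
      bad <- rep(FALSE, length(seqs))
      for (m in depletion) {
        rx <- iupac_to_regex(m); rrx <- iupac_to_regex(revcomp_iupac(m))
        bad <- bad | grepl(rx, seqs, perl = TRUE) |
          grepl(rrx, seqs, perl = TRUE)
      }
      rx <- paste0("(?=", iupac_to_regex("GTGNGAA"), ")")
      rrx <- paste0("(?=", iupac_to_regex(revcomp_iupac("GTGNGAA")), ")")
      n_suh <- vapply(seq_along(seqs), function(i) {
        a <- gregexpr(rx, seqs[i], perl = TRUE)[[1]]
        b <- gregexpr(rrx, seqs[i], perl = TRUE)[[1]]
        (if (a[1] == -1L) 0L else length(a)) +
          (if (b[1] == -1L) 0L else length(b))
      }, integer(1))
      bad | n_suh > 1L
    }
    ids <- c(sprintf("test%04d", seq_len(n_test)),
             sprintf("ctrl%04d", seq_len(n_control)))
    set <- rep(c("test", "control"), c(n_test, n_control))
    planted <- stats::runif(n_test + n_control) <
      ifelse(set == "test", base_presence + msr_effect, base_presence)
    seqs <- gen_batch(n_test + n_control)
    is_test <- set == "test"
    for (i in which(is_test)) {
      pos <- sample.int(block_len - 7L, 1L)
      seqs[i] <- overwrite_at(seqs[i], pos, instantiate_iupac("CAGGTAR"))
      if (planted[i]) seqs[i] <- plant_ca(seqs[i], pos, pos + 7L)
    }
    seqs[!is_test & planted] <- vapply(seqs[!is_test & planted], plant_ca,
                                       character(1), USE.NAMES = FALSE)
    repeat {
      ctrl_idx <- which(!is_test)
      bad <- control_bad(seqs[ctrl_idx])
      if (!any(bad)) break
      redo <- ctrl_idx[bad]
      seqs[redo] <- gen_batch(length(redo))
      seqs[redo][planted[redo]] <- vapply(seqs[redo][planted[redo]],
                                          plant_ca, character(1),
                                          USE.NAMES = FALSE)
    }
    list(blocks = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
         truth = data.frame(id = ids, set = set, planted_msr = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Ortholog benchmark for the aligner
#'
#' `n` random blocks in "genome A" and their diverged copies in "genome B"
#' (shuffled order), with the planted one-to-one mapping as truth.
#'
#' @param n Number of block pairs.
#' @param block_len Block length in bp.
#' @param divergence Per-bp substitution probability.
#' @param indel_rate Expected indels per bp.
#' @param seed Mandatory integer seed.
#' @return List: `blocks_a`, `blocks_b` (data frames `id`, `seq`), `truth`
#'   (data frame `id_a`, `id_b`).
#' @export
make_ortholog_benchmark <- function(n, block_len = 600L, divergence = 0.25,
                                    indel_rate = 0.01, seed) {
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n + 1L)
    recs_a <- lapply(seq_len(n), function(i) {
      seq_record(sprintf("ga%03d", i),
                 paste(random_bases(block_len), collapse = ""))
    })
    recs_b <- lapply(seq_len(n), function(i) {
      make_ortholog_pair(recs_a[[i]], divergence, indel_rate,
                         seed = sub_seeds[i], id = sprintf("gb%03d", i))
    })
    ord <- sample.int(n)
    list(
      blocks_a = data.frame(
        id = vapply(recs_a, `[[`, character(1), "id"),
        seq = vapply(recs_a, `[[`, character(1), "seq"),
        stringsAsFactors = FALSE),
      blocks_b = data.frame(
        id = vapply(recs_b[ord], `[[`, character(1), "id"),
        seq = vapply(recs_b[ord], `[[`, character(1), "seq"),
        stringsAsFactors = FALSE),
      truth = data.frame(id_a = sprintf("ga%03d", seq_len(n)),
                         id_b = sprintf("gb%03d", seq_len(n)),
                         stringsAsFactors = FALSE))
  })
}
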