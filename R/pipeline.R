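# End-to-end analyses. Each runner executes the stage chain of one of the
# study designs, records stage counts in a manifest (so the flowchart
# identities can be audited: every input block ends up in exactly one of
# test/control/dropped, etc.) and optionally writes BED/TSV/JSON outputs.

new_set_partition <- function(test_ids, control_ids, dropped_ids, criteria) {
  structure(list(test_ids = test_ids, control_ids = control_ids,
                 dropped_ids = dropped_ids, criteria = criteria),
            class = "set_partition")
}

write_outputs <- function(out_dir, manifest, tables) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(tables)) {
    write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  invisible(out_dir)
}

#' Notch-target embryonic vs non-embryonic enrichment analysis
#'
#' Stage chain: Su(H) block extraction in both genomes; all-vs-all alignment
#' of genome-A blocks against genome-B blocks at `evalue_max`; the conserved
#' genome-A blocks are partitioned into a Zelda-positive test set and a
#' depleted control set; MSR-class enrichment (Fisher + permutation) is
#' tested between the sets and the conservation E-value distributions are
#' compared.
#'
#' @param records_a,records_b Genome/contig record lists for the two
#'   species.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Conservation E-value cutoff (default `1e-15`).
#' @param flank,merge_threshold Block-extraction parameters.
#' @param msr_classes MSR classes to test.
#' @param n_perm Permutations per enrichment test.
#' @param seed Seed for the permutation streams.
#' @param out_dir Optional output directory (manifest + TSV tables).
#' @return List: `blocks_a`, `hits`, `partition`, `enrichment` (list per
#'   class), `evalue_check`, `manifest`.
#' @export
run_notch_embryonic_analysis <- function(records_a, records_b,
                                         scheme = scoring_scheme(),
                                         evalue_max = 1e-15,
                                         flank = 296L,
                                         merge_threshold = 2L * flank,
                                         msr_classes = c("CA_dinuc",
                                                         "CAR_trinuc"),
                                         n_perm = 2000L, seed = 1L,
                                         out_dir = NULL) {
  blocks_a <- extract_blocks(records_a, "SuH", flank, merge_threshold)
  blocks_b <- extract_blocks(records_b, "SuH", flank, merge_threshold)
  if (nrow(blocks_a) == 0L || nrow(blocks_b) == 0L) {
    manifest <- list(stage = "extract_blocks",
                     n_blocks_a = nrow(blocks_a),
                     n_blocks_b = nrow(blocks_b),
                     outcome = "no blocks")
    return(list(blocks_a = blocks_a, hits = empty_alignment_hits(),
                partition = NULL, enrichment = list(),
                evalue_check = NULL, manifest = manifest))
  }
  hits <- all_vs_all(blocks_a, blocks_b, scheme, evalue_max)
  bp <- best_partner(hits)
  conserved <- blocks_a[blocks_a$id %in% bp$query_id, , drop = FALSE]
  if (nrow(conserved) == 0L) stop("alignment stage: no conserved blocks")
  partition <- partition_blocks(conserved)
  if (length(partition$test_ids) == 0L || length(partition$control_ids) == 0L) {
    stop("partition stage: empty test or control set")
  }
  enrichment <- lapply(msr_classes, function(cl) {
    enrichment_test(partition, conserved, cl, n_perm = n_perm, seed = seed)
  })
  names(enrichment) <- msr_classes
  ev <- stats::setNames(rep(NA_real_, nrow(conserved)), conserved$id)
  best <- hits[order(hits$query_id, hits$evalue), , drop = FALSE]
  best <- best[!duplicated(best$query_id), , drop = FALSE]
  ev[best$query_id] <- best$evalue
  evalue_check <- evalue_distribution_check(partition, ev)
  manifest <- list(
    parameters = list(flank = flank, merge_threshold = merge_threshold,
                      evalue_max = evalue_max, n_perm = n_perm, seed = seed),
    counts = list(
      n_blocks_a = nrow(blocks_a), n_blocks_b = nrow(blocks_b),
      n_conserved = nrow(conserved),
      n_test = length(partition$test_ids),
      n_control = length(partition$control_ids),
      n_dropped = length(partition$dropped_ids)),
    enrichment = lapply(enrichment, function(e) {
      list(table = as.list(e$table), odds_ratio = e$odds_ratio,
           p_fisher = e$p_fisher, p_perm = e$p_perm)
    })
  )
  stopifnot(manifest$counts$n_test + manifest$counts$n_control +
              manifest$counts$n_dropped == manifest$counts$n_conserved)
  write_outputs(out_dir, manifest, list(
    blocks_a = blocks_a[, setdiff(names(blocks_a), "seq")],
    hits = hits[, setdiff(names(hits), "edit")]))
  list(blocks_a = blocks_a, hits = hits, partition = partition,
       enrichment = enrichment, evalue_check = evalue_check,
       manifest = manifest)
}

#' A/P embryonic enhancer enrichment analysis
#'
#' Stage chain: Zelda-centred block extraction in both genomes; all-vs-all
#' alignment at `evalue_max` (default `1e-40`); restriction to blocks that
#' also carry a Runt site (`AACCRCA`, both strands); reciprocal-best-hit
#' filtering between the two genomes; per-species MSR-class enrichment with
#' the species-A reciprocal blocks as test set and their species-B partners
#' as control.
#'
#' @inheritParams run_notch_embryonic_analysis
#' @param half_width Zelda block half-width (default 300).
#' @return List: `blocks_a`, `blocks_b`, `reciprocal`, `enrichment`,
#'   `manifest`.
#' @export
run_ap_embryonic_analysis <- function(records_a, records_b,
                                      scheme = scoring_scheme(),
                                      evalue_max = 1e-40,
                                      half_width = 300L,
                                      msr_classes = c("CA_dinuc",
                                                      "CAR_trinuc",
                                                      "AG_dinuc", "T_run"),
                                      n_perm = 2000L, seed = 1L,
                                      out_dir = NULL) {
  blocks_a <- zelda_blocks(records_a, half_width)
  blocks_b <- zelda_blocks(records_b, half_width)
  if (nrow(blocks_a) == 0L || nrow(blocks_b) == 0L) {
    return(list(blocks_a = blocks_a, blocks_b = blocks_b,
                reciprocal = NULL, enrichment = list(),
                manifest = list(stage = "zelda_blocks",
                                outcome = "no blocks")))
  }
  has_runt <- function(blocks) {
    vapply(seq_len(nrow(blocks)), function(i) {
      nrow(scan_motif(seq_record(blocks$id[i], blocks$seq[i]),
                      "Runt", "both")) > 0L
    }, logical(1))
  }
  runt_a <- blocks_a[has_runt(blocks_a), , drop = FALSE]
  runt_b <- blocks_b[has_runt(blocks_b), , drop = FALSE]
  if (nrow(runt_a) == 0L || nrow(runt_b) == 0L) {
    stop("runt filter stage: no Runt-positive blocks")
  }
  hits_ab <- all_vs_all(runt_a, runt_b, scheme, evalue_max)
  hits_ba <- all_vs_all(runt_b, runt_a, scheme, evalue_max)
  recip <- reciprocal_homologs(hits_ab, hits_ba)
  if (nrow(recip) == 0L) stop("reciprocal stage: no reciprocal homologs")
  combined <- rbind(runt_a, runt_b)
  partition <- new_set_partition(
    test_ids = recip$id_a, control_ids = recip$id_b,
    dropped_ids = setdiff(combined$id, c(recip$id_a, recip$id_b)),
    criteria = list(design = "species-A reciprocal blocks vs species-B partners"))
  enrichment <- lapply(msr_classes, function(cl) {
    enrichment_test(partition, combined, cl, n_perm = n_perm, seed = seed)
  })
  names(enrichment) <- msr_classes
  manifest <- list(
    parameters = list(half_width = half_width, evalue_max = evalue_max,
                      n_perm = n_perm, seed = seed),
    counts = list(
      n_blocks_a = nrow(blocks_a), n_blocks_b = nrow(blocks_b),
      n_runt_a = nrow(runt_a), n_runt_b = nrow(runt_b),
      n_hits_ab = nrow(hits_ab), n_hits_ba = nrow(hits_ba),
      n_reciprocal = nrow(recip)),
    enrichment = lapply(enrichment, function(e) {
      list(table = as.list(e$table), odds_ratio = e$odds_ratio,
           p_fisher = e$p_fisher, p_perm = e$p_perm)
    })
  )
  write_outputs(out_dir, manifest,
                list(reciprocal = recip,
                     hits_ab = hits_ab[, setdiff(names(hits_ab), "edit")]))
  list(blocks_a = blocks_a, blocks_b = blocks_b, reciprocal = recip,
       enrichment = enrichment, manifest = manifest)
}

#' Per-enhancer NEE architecture and MSR-content report
#'
#' For each input sequence: NEE candidates (linked pair + Su(H)), site
#' annotation tracks, tandem-repeat tracts, and the MSR content of a
#' `width` bp window centred on the heterotypic site cluster (whole
#' sequence when no candidate grammar is found, reported as
#' `"no candidate"`).
#'
#' @param records Enhancer `seq_record` list.
#' @param width Content window width (default 400).
#' @param out_dir Optional output directory (site BED, tract BED, content
#'   TSV).
#' @return List: `content` (data frame seq_id, status, window coordinates,
#'   spacer_len, msr_content), `candidates`, `sites` (BED-style data
#'   frame), `tracts`.
#' @export
run_nee_report <- function(records, width = 400L, out_dir = NULL) {
  records <- as_record_list(records)
  content <- list(); cands <- list(); sites <- list(); tracts <- list()
  for (rec in records) {
    nees <- find_nees(rec)
    tr <- find_tandem_repeats(rec)
    tr$name <- sprintf("%sx%d", tr$unit_seq, tr$copies)
    tracts[[rec$id]] <- tr
    for (m in c("SuH", "Twi:Da", "Dorsal_core", "Snail", "Zelda", "SMMSE")) {
      h <- scan_motif(rec, m, "both")
      if (nrow(h)) {
        sites[[paste(rec$id, m)]] <- data.frame(
          seq_id = rec$id, start = h$start, end = h$end,
          name = m, score = 0L, strand = h$strand,
          stringsAsFactors = FALSE)
      }
    }
    if (nrow(nees) == 0L) {
      content[[rec$id]] <- data.frame(
        seq_id = rec$id, status = "no candidate",
        window_start = 0L, window_end = rec$length,
        spacer_len = NA_integer_,
        msr_content = msr_content(rec, c(0L, rec$length), tracts = tr),
        stringsAsFactors = FALSE)
    } else {
      cands[[rec$id]] <- nees
      win <- center_window_on_cluster(nees[1L, ], rec, width)
      content[[rec$id]] <- data.frame(
        seq_id = rec$id, status = "candidate",
        window_start = win$interval$start, window_end = win$interval$end,
        spacer_len = nees$spacer_len[1L],
        msr_content = msr_content(rec, win$interval, tracts = tr),
        stringsAsFactors = FALSE)
    }
  }
  content <- do.call(rbind, content); rownames(content) <- NULL
  sites <- if (length(sites)) do.call(rbind, sites) else NULL
  if (!is.null(sites)) rownames(sites) <- NULL
  all_tracts <- do.call(rbind, tracts); rownames(all_tracts) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sites)) write_bed(sites, file.path(out_dir, "sites.bed"))
    write_bed(all_tracts, file.path(out_dir, "tracts.bed"))
    write_tsv(content, file.path(out_dir, "msr_content.tsv"))
  }
  list(content = content, candidates = cands, sites = sites,
       tracts = all_tracts)
}
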