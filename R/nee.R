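# Neurogenic Ectoderm Enhancer (NEE) grammar discovery: a linked
# Twist:Daughterless site (CACATGT) and Dorsal core (GGAAABYCC) separated by a
# bounded spacer, plus a Su(H) site (YGTGRGAA) nearby. The spacer length is
# the key functional variable of this enhancer class.

#' Find linked Twist-Dorsal site pairs
#'
#' Canonical semantics enumerate *all* placements (overlapping included) where
#' a Twist:Da match and a Dorsal-core match occur with between `spacer_min`
#' and `spacer_max` intervening bases. With `any_orientation` both motifs are
#' searched on both strands and the pair is accepted in either left-right
#' order. The `"grep"` dialect instead reproduces a single leftmost,
#' non-overlapping pass of the shell regular expression
#' `CACATGT.{0,spacer_max}GGAAA[^A][CT]CC` over the sequence and its reverse
#' complement (a subset of the exhaustive enumeration).
#'
#' @param record A `seq_record` (or plain DNA string).
#' @param spacer_min,spacer_max Spacer bounds in bp (defaults 0 and 41).
#' @param dorsal_motif Dorsal search motif (default the 9-mer core
#'   `GGAAABYCC`).
#' @param any_orientation Search both strands and both site orders.
#' @param dialect `"exhaustive"` (default) or `"grep"`.
#' @return Data frame with one row per placement: `seq_id`, `twist_start`,
#'   `twist_end`, `twist_strand`, `dorsal_start`, `dorsal_end`,
#'   `dorsal_strand`, `spacer_len`, `order` (`"TD"` if Twist precedes Dorsal).
#' @export
find_linked_pairs <- function(record, spacer_min = 0L, spacer_max = 41L,
                              dorsal_motif = "GGAAABYCC",
                              any_orientation = TRUE,
                              dialect = c("exhaustive", "grep")) {
  dialect <- match.arg(dialect)
  if (spacer_max < spacer_min) stop("spacer_max must be >= spacer_min")
  if (is.character(record)) record <- seq_record("<seq>", record)
  if (dialect == "grep") {
    return(linked_pairs_grep(record, spacer_min, spacer_max))
  }
  strands <- if (any_orientation) "both" else "plus"
  tw <- scan_motif(record, "Twi:Da", strands)
  do <- scan_motif(record, dorsal_motif, strands)
  out <- list()
  for (i in seq_len(nrow(tw))) {
    for (j in seq_len(nrow(do))) {
      if (tw$end[i] <= do$start[j]) {
        spacer <- do$start[j] - tw$end[i]
        ord <- "TD"
      } else if (do$end[j] <= tw$start[i]) {
        if (!any_orientation) next
        spacer <- tw$start[i] - do$end[j]
        ord <- "DT"
      } else {
        next # overlapping sites are not a linked pair
      }
      if (spacer < spacer_min || spacer > spacer_max) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = record$id,
        twist_start = tw$start[i], twist_end = tw$end[i],
        twist_strand = tw$strand[i],
        dorsal_start = do$start[j], dorsal_end = do$end[j],
        dorsal_strand = do$strand[j],
        spacer_len = spacer, order = ord, stringsAsFactors = FALSE)
    }
  }
  finish_pairs(out)
}

linked_pairs_grep <- function(record, spacer_min, spacer_max) {
  pat <- sprintf("CACATGT[ACGT]{%d,%d}GGAAA[CGT][CT]CC", spacer_min, spacer_max)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") record$seq else revcomp(record$seq)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      st <- starts[k]; len <- lens[k]
      if (strand == "+") {
        row <- data.frame(
          seq_id = record$id,
          twist_start = st, twist_end = st + 7L, twist_strand = "+",
          dorsal_start = st + len - 9L, dorsal_end = st + len,
          dorsal_strand = "+",
          spacer_len = len - 16L, order = "TD", stringsAsFactors = FALSE)
      } else {
        # map the reverse-complement interval [a, b) to plus [L-b, L-a)
        t0 <- record$length - (st + 7L)
        d0 <- record$length - (st + len)
        row <- data.frame(
          seq_id = record$id,
          twist_start = t0, twist_end = t0 + 7L, twist_strand = "-",
          dorsal_start = d0, dorsal_end = d0 + 9L, dorsal_strand = "-",
          spacer_len = len - 16L, order = "DT", stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  finish_pairs(out)
}

finish_pairs <- function(out) {
  if (!length(out)) {
    return(data.frame(seq_id = character(0), twist_start = integer(0),
                      twist_end = integer(0), twist_strand = character(0),
                      dorsal_start = integer(0), dorsal_end = integer(0),
                      dorsal_strand = character(0), spacer_len = integer(0),
                      order = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(pmin(out$twist_start, out$dorsal_start), out$spacer_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find NEE candidates
#'
#' Each linked Twist-Dorsal pair is promoted to an NEE candidate when at least
#' one Su(H) site (both strands) has its nearest edge within `suh_window` bp
#' of the pair span; the nearest Su(H) site is attached. `suh_distance` is the
#' gap in bp between the Su(H) site edge and the nearest edge of the pair,
#' negative when the Su(H) site lies to the left, zero when it overlaps the
#' span.
#'
#' Annotation counts (Snail, Zelda, SMMSE, full Dorsal sites, extra Twist and
#' Su(H) sites over the whole record) are attached as columns; the full
#' annotation hit tables are available via `attr(x, "annotations")`.
#'
#' @param record A `seq_record` (or plain DNA string).
#' @param suh_window Maximum Su(H) distance in bp (default 300).
#' @param ... Passed to [find_linked_pairs()].
#' @return Data frame with one row per candidate.
#' @export
find_nees <- function(record, suh_window = 300L, ...) {
  if (is.character(record)) record <- seq_record("<seq>", record)
  pairs <- find_linked_pairs(record, ...)
  suh <- scan_motif(record, "SuH", "both")
  out <- list()
  ann_list <- list()
  ann <- nee_annotations(record)
  for (i in seq_len(nrow(pairs))) {
    span_lo <- min(pairs$twist_start[i], pairs$dorsal_start[i])
    span_hi <- max(pairs$twist_end[i], pairs$dorsal_end[i])
    if (nrow(suh) == 0L) next
    gap_left <- span_lo - suh$end    # >0 when Su(H) entirely left of span
    gap_right <- suh$start - span_hi # >0 when entirely right
    dist <- ifelse(gap_left > 0, -gap_left, ifelse(gap_right > 0, gap_right, 0L))
    best <- which.min(abs(dist))
    if (abs(dist[best]) > suh_window) next
    row <- pairs[i, , drop = FALSE]
    row$locus_start <- span_lo
    row$locus_end <- span_hi
    row$suh_start <- suh$start[best]
    row$suh_end <- suh$end[best]
    row$suh_strand <- suh$strand[best]
    row$suh_distance <- as.integer(dist[best])
    for (nm in names(ann)) row[[paste0("n_", nm)]] <- nrow(ann[[nm]])
    out[[length(out) + 1L]] <- row
    ann_list[[length(ann_list) + 1L]] <- ann
  }
  if (!length(out)) {
    res <- cbind(finish_pairs(list()),
                 data.frame(locus_start = integer(0), locus_end = integer(0),
                            suh_start = integer(0), suh_end = integer(0),
                            suh_strand = character(0),
                            suh_distance = integer(0)))
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  attr(res, "annotations") <- ann_list
  res
}

# Motif annotation tracks scanned over the whole record.
nee_annotations <- function(record) {
  list(
    snail = scan_motif(record, "Snail", "both"),
    zelda = scan_motif(record, "Zelda", "both"),
    smmse = scan_motif(record, "SMMSE", "both"),
    dorsal_full = scan_motif(record, "Dorsal_Dbeta", "both"),
    twist = scan_motif(record, "Twi:Da", "both"),
    suh = scan_motif(record, "SuH", "both")
  )
}

#' Scan for the Schnurri/Mad/Medea Silencer Element
#'
#' Both-strand scan with the 19-mer SMMSE consensus `MYGGCGWCACACTGTCTGS`.
#' The element marks Dpp-constrained (non-"pure") NEEs such as the one at
#' *vnd*.
#'
#' @param record A `seq_record` (or plain DNA string).
#' @return Hit data frame as from [scan_motif()].
#' @export
annotate_smmse <- function(record) {
  scan_motif(record, "SMMSE", "both")
}
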