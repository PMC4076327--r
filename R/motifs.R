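# IUPAC-degenerate motif scanning. Matching is by exact degenerate strings
# (no PWM scoring): an IUPAC letter expands to a character class over
# {A,C,G,T}. A motif N deliberately matches {A,C,G,T} but *not* a sequence N,
# so assembly gaps can never create motif hits.

.IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Built-in binding-motif registry
#'
#' The degenerate binding motifs used throughout the pipeline, exactly as
#' printed in the source study: Su(H) (`YGTGRGAA`), the relaxed Su(H) string
#' used for control-set depletion (`GTGNGAA`), Zelda (`CAGGTAR`) and its three
#' depletion variants, the Twist:Daughterless E-box (`CACATGT`), the Dorsal
#' 9-mer search core plus the full and relaxed 11-mer site, Snail, Runt, and
#' the 19-mer Schnurri/Mad/Medea Silencer Element (SMMSE).
#'
#' @return Data frame with columns `name`, `iupac`, `source`.
#' @export
builtin_motifs <- function() {
  data.frame(
    name = c("SuH", "SuH_relaxed",
             "Zelda", "Zelda_variant1", "Zelda_variant2", "Zelda_variant3",
             "Twi:Da", "Dorsal_core", "Dorsal_Dbeta", "Dorsal_relaxed",
             "Snail", "Runt", "SMMSE"),
    iupac = c("YGTGRGAA", "GTGNGAA",
              "CAGGTAR", "CAGGTA", "CAGGCAR", "TAGGTAR",
              "CACATGT", "GGAAABYCC", "VGGAAABYCCV", "VGGAAABNCCV",
              "CARRTG", "AACCRCA", "MYGGCGWCACACTGTCTGS"),
    source = c("Su(H)/Notch pathway anchor site",
               "relaxed Su(H) string used to deplete control blocks",
               "Zelda pioneer activator (perfect site)",
               "Zelda depletion variant", "Zelda depletion variant",
               "Zelda depletion variant",
               "Twist:Daughterless bHLH heterodimer E-box",
               "Dorsal search core (9-mer)",
               "Dorsal full site (Dbeta 11-mer)",
               "Dorsal full site relaxed at the Y position",
               "Snail mesodermal repressor",
               "Runt A/P repressor",
               "Schnurri/Mad/Medea Silencer Element consensus"),
    stringsAsFactors = FALSE
  )
}

# Resolve a motif argument: either a registry name or a raw IUPAC string.
resolve_motif <- function(motif) {
  reg <- builtin_motifs()
  if (motif %in% reg$name) {
    list(name = motif, iupac = reg$iupac[reg$name == motif])
  } else {
    validate_iupac(motif)
    list(name = motif, iupac = motif)
  }
}

validate_iupac <- function(iupac) {
  if (!is.character(iupac) || length(iupac) != 1L || !nzchar(iupac)) {
    stop("motif must be a nonempty IUPAC string")
  }
  ch <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(.IUPAC_CLASS))
  if (any(bad)) {
    stop(sprintf("invalid IUPAC code '%s' in motif '%s'", ch[bad][1], iupac))
  }
  invisible(toupper(iupac))
}

#' Convert an IUPAC motif to a plain regular expression
#' @param iupac IUPAC motif string.
#' @return Regular expression over `{A,C,G,T}` character classes.
#' @export
iupac_to_regex <- function(iupac) {
  ch <- strsplit(validate_iupac(iupac), "", fixed = TRUE)[[1]]
  paste(.IUPAC_CLASS[ch], collapse = "")
}

#' Reverse complement of an IUPAC motif
#' @param iupac IUPAC motif string.
#' @return IUPAC string matching the reverse complement.
#' @export
revcomp_iupac <- function(iupac) {
  ch <- strsplit(validate_iupac(iupac), "", fixed = TRUE)[[1]]
  paste(rev(.IUPAC_COMPLEMENT[ch]), collapse = "")
}

# All (overlapping) start positions of a fixed-length regex, 0-based.
regex_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every position where the motif (or, for the minus strand, its
#' reverse complement) matches, including overlapping matches. Coordinates are
#' always on the plus strand; `matched_text` carries plus-strand letters.
#' A palindromic interval matching on both strands is reported once per
#' strand; downstream set logic works on intervals.
#'
#' @param record A `seq_record` (or plain DNA string).
#' @param motif Registry name or IUPAC string.
#' @param strands `"both"` (default), `"plus"`, or `"minus"`.
#' @return Data frame of hits: `motif_name`, `seq_id`, `start`, `end`,
#'   `strand`, `matched_text`, sorted by `start` then strand.
#' @export
scan_motif <- function(record, motif, strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (is.character(record)) record <- seq_record("<seq>", record)
  m <- resolve_motif(motif)
  L <- nchar(m$iupac)
  hits <- list()
  if (strands %in% c("both", "plus")) {
    st <- regex_starts(record$seq, iupac_to_regex(m$iupac))
    if (length(st)) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = m$name, seq_id = record$id,
        start = st, end = st + L, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "minus")) {
    st <- regex_starts(record$seq, iupac_to_regex(revcomp_iupac(m$iupac)))
    if (length(st)) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = m$name, seq_id = record$id,
        start = st, end = st + L, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  if (nrow(out)) {
    out$matched_text <- substring(record$seq, out$start + 1L, out$end)
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_hits <- function() {
  data.frame(motif_name = character(0), seq_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Count motif hits per record
#'
#' @param records List of `seq_record`.
#' @param motif Registry name or IUPAC string.
#' @param strands Strand selection as in [scan_motif()].
#' @return Data frame `seq_id`, `n_hits` (one row per record, input order).
#' @export
count_hits <- function(records, motif, strands = "both") {
  records <- as_record_list(records)
  data.frame(
    seq_id = vapply(records, `[[`, character(1), "id"),
    n_hits = vapply(records, function(r) nrow(scan_motif(r, motif, strands)),
                    integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
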