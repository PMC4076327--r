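#' @useDynLib msrfoot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinates are 0-based half-open everywhere inside the package; BED output
# inherits this convention directly. 1-based positions appear only in
# human-readable report text.

.VALID_BASES <- c("A", "C", "G", "T", "N")
# IUPAC ambiguity codes other than N occurring in *input sequences* are
# normalized to N (assemblies occasionally carry them); anything else is an
# error with its position.
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Create a DNA sequence record
#'
#' The universal input object of the pipeline: a named DNA sequence with
#' optional provenance. Sequences are normalized to upper case over the
#' alphabet `{A,C,G,T,N}` (`U` becomes `T`; other IUPAC ambiguity letters
#' become `N`; anything else is rejected with its 1-based position).
#'
#' @param id Non-empty record identifier.
#' @param seq DNA string.
#' @param description Optional free-text description.
#' @param species Optional species label.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `seq`, `species`, `length`.
#' @export
seq_record <- function(id, seq, description = "", species = NA_character_) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("record id must be a nonempty string")
  }
  seq <- normalize_seq(seq, id = id)
  structure(
    list(id = id, description = description, seq = seq,
         species = species, length = nchar(seq)),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)%s\n", x$id, x$length,
              if (!is.na(x$species)) paste0(" [", x$species, "]") else ""))
  invisible(x)
}

#' Normalize a DNA string
#'
#' Upper-cases, maps `U` to `T`, collapses IUPAC ambiguity letters (other than
#' `N`) to `N`, and rejects any remaining non-IUPAC character, reporting its
#' position.
#'
#' @param seq A single DNA string.
#' @param id Record id used in error messages.
#' @return Normalized string over `{A,C,G,T,N}`.
#' @export
normalize_seq <- function(seq, id = "<seq>") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("seq must be a single string")
  }
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c(.VALID_BASES, .IUPAC_AMBIG))
  if (any(bad)) {
    pos <- which(bad)[1]
    stop(sprintf("illegal character '%s' at position %d in record '%s'",
                 ch[pos], pos, id))
  }
  ch[ch %in% .IUPAC_AMBIG] <- "N"
  paste(ch, collapse = "")
}

#' Read a FASTA file
#'
#' One `seq_record` per header, in file order. Sequences are normalized (see
#' [normalize_seq()]). Empty files and duplicate ids are errors.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species label attached to every record.
#' @return List of `seq_record`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no records in FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate record id in %s: '%s'", path, dup[1]))
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- seq_record(ids[i], as.character(set[[i]]),
                           description = desc[i], species = species)
  }
  names(out) <- ids
  out
}

#' Write records to a FASTA file
#'
#' @param records List of `seq_record`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_record_list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    hdr <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else {
      rec$id
    }
    writeLines(paste0(">", hdr), con)
    starts <- seq(1L, rec$length, by = width)
    writeLines(substring(rec$seq, starts, pmin(starts + width - 1L, rec$length)),
               con)
  }
  invisible(path)
}

# Accept a single record or a list of records; always return a named list.
as_record_list <- function(records) {
  if (inherits(records, "seq_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "seq_record")))
  names(records) <- vapply(records, `[[`, character(1), "id")
  records
}

#' Reverse complement
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement (an involution).
#' @export
revcomp <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("revcomp: sequence must be over {A,C,G,T,N}")
  ch <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(ch, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract a window centred on a position
#'
#' Returns up to `half_width` bases on each side of `center`, clipped to the
#' record; the `truncated` flag records whether either edge was clipped (such
#' sequences are kept, mirroring how contig-edge blocks are retained in the
#' genome-wide census).
#'
#' @param record A `seq_record`.
#' @param center 0-based position, `0 <= center < record$length`.
#' @param half_width Positive flank size in bp.
#' @return List with `seq`, `interval` (data frame: seq_id, start, end,
#'   strand), and `truncated`.
#' @export
extract_window <- function(record, center, half_width) {
  stopifnot(inherits(record, "seq_record"))
  if (half_width <= 0) stop("half_width must be > 0")
  if (center < 0 || center >= record$length) {
    stop(sprintf("center %d out of range [0, %d)", center, record$length))
  }
  start <- max(0L, as.integer(center - half_width))
  end <- min(record$length, as.integer(center + half_width))
  list(
    seq = substr(record$seq, start + 1L, end),
    interval = interval_df(record$id, start, end),
    truncated = (center - half_width < 0) || (center + half_width > record$length)
  )
}

# Small constructor for the interval data-frame representation used throughout
# (0-based half-open, plus-strand unless stated).
interval_df <- function(seq_id, start, end, strand = "+") {
  data.frame(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df Data frame with columns `seq_id`, `start`, `end`, plus optional
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  bed <- data.frame(df$seq_id, df$start, df$end, name, score, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic generators in the package route through
# this, so results are a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
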