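# Direct tandem repeat (microsatellite, MSR) detection. A repeat tract is two
# or more head-to-tail copies of a unit of 2-50 bp. Two semantics are
# provided:
#
#  * "exhaustive" (canonical): every position i and unit length u where
#    seq[i, i+u) == seq[i+u, i+2u) seeds a tract; seeds are extended rightward
#    by whole-unit copies and only maximal (interval, unit_len) tracts are
#    reported (tracts contained in another tract with the same unit length are
#    dropped). This is a stable mathematical definition independent of any
#    regex engine's traversal order.
#
#  * "regex_single_pass": leftmost, greedy-unit, non-overlapping matches of
#    the backtracking pattern "(.{min,max})\1", reproducing what a single
#    grep/perl pass reports.
#
# Exhaustive coverage is a superset of single-pass coverage on every input.
# Homopolymer runs (unit length 1) are excluded by default; N breaks tracts.

#' Find direct tandem repeats
#'
#' @param record A `seq_record` (or plain DNA string).
#' @param unit_min,unit_max Unit length bounds in bp (defaults 2 and 50).
#' @param semantics `"exhaustive"` (default) or `"regex_single_pass"`.
#' @return Data frame of tracts: `seq_id`, `start`, `end`, `unit_len`,
#'   `unit_seq`, `copies`, sorted by `start`, `unit_len`. Intervals contain
#'   whole copies only (a partial trailing copy never extends a tract).
#' @export
find_tandem_repeats <- function(record, unit_min = 2L, unit_max = 50L,
                                semantics = c("exhaustive", "regex_single_pass")) {
  semantics <- match.arg(semantics)
  if (is.character(record)) record <- seq_record("<seq>", record)
  if (unit_min < 1L) stop("unit_min must be >= 1")
  if (unit_max < unit_min) stop("unit_max must be >= unit_min")
  if (semantics == "regex_single_pass") {
    return(tandem_regex_pass(record, unit_min, unit_max))
  }
  ch <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  ok <- ch != "N"
  starts <- integer(0); units <- integer(0); copies <- integer(0)
  u_hi <- min(unit_max, L %/% 2L)
  if (u_hi < unit_min) return(finish_tracts2(record, starts, units, copies))
  for (u in unit_min:u_hi) {
    eq <- ch[seq_len(L - u)] == ch[(u + 1L):L] &
      ok[seq_len(L - u)] & ok[(u + 1L):L]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values & r$lengths >= u)
    for (k in keep) {
      a <- run_start[k] - 1L          # 0-based start of the match run
      m <- r$lengths[k]               # run length: seq[a+j] == seq[a+j+u]
      # Maximal tracts start at offsets r where the tract end sets a new
      # record; only offsets r < u can do so (later ones repeat an earlier
      # end with a later start, hence are contained).
      offs <- 0:min(u - 1L, m - u)
      ends <- a + offs + u * ((m - offs + u) %/% u)
      rec_best <- cummax(c(-1L, ends[-length(ends)]))
      sel <- offs[ends > rec_best]
      starts <- c(starts, a + sel)
      units <- c(units, rep.int(u, length(sel)))
      copies <- c(copies, (m - sel + u) %/% u)
    }
  }
  finish_tracts2(record, starts, units, copies)
}

tandem_regex_pass <- function(record, unit_min, unit_max) {
  pat <- sprintf("([ACGT]{%d,%d})\\1", unit_min, unit_max)
  m <- gregexpr(pat, record$seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(finish_tracts(list()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  u <- lens %/% 2L
  finish_tracts(list(data.frame(
    seq_id = record$id, start = starts, end = starts + lens,
    unit_len = u,
    unit_seq = substring(record$seq, starts + 1L, starts + u),
    copies = 2L, stringsAsFactors = FALSE)))
}

finish_tracts2 <- function(record, starts, units, copies) {
  if (length(starts) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit_len = integer(0),
                      unit_seq = character(0), copies = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    seq_id = rep.int(record$id, length(starts)),
    start = starts, end = starts + units * copies,
    unit_len = units,
    unit_seq = substring(record$seq, starts + 1L, starts + units),
    copies = copies, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

finish_tracts <- function(res) {
  if (!length(res)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit_len = integer(0),
                      unit_seq = character(0), copies = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base MSR mask
#'
#' Union of the tract intervals: `mask[p]` is `TRUE` iff position `p`
#' (0-based) is covered by at least one repeat tract.
#'
#' @param record A `seq_record`.
#' @param tracts Tract data frame from [find_tandem_repeats()]; computed with
#'   default (exhaustive) semantics when omitted.
#' @return Logical vector of length `record$length`.
#' @export
msr_mask <- function(record, tracts = NULL) {
  if (is.character(record)) record <- seq_record("<seq>", record)
  if (is.null(tracts)) tracts <- find_tandem_repeats(record)
  mask <- logical(record$length)
  for (i in seq_len(nrow(tracts))) {
    mask[(tracts$start[i] + 1L):tracts$end[i]] <- TRUE
  }
  mask
}

#' Windowed MSR content
#'
#' Fraction of window positions covered by the MSR mask — the pipeline's
#' headline statistic (the Hawaiian "pure" NEEs sit in the 43-57% range over
#' a 400 bp window; non-Hawaiian counterparts near 32-38%).
#'
#' @param record A `seq_record`.
#' @param window 0-based half-open window: either `c(start, end)` or a data
#'   frame with `start`/`end` columns.
#' @param tracts Optional precomputed tracts (exhaustive semantics otherwise).
#' @param semantics Tract semantics when `tracts` is omitted.
#' @return Fraction in `[0, 1]`.
#' @export
msr_content <- function(record, window, tracts = NULL,
                        semantics = "exhaustive") {
  if (is.character(record)) record <- seq_record("<seq>", record)
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (start < 0 || end > record$length || start >= end) {
    stop(sprintf("window [%d,%d) outside record '%s' [0,%d)",
                 start, end, record$id, record$length))
  }
  if (is.null(tracts)) {
    tracts <- find_tandem_repeats(record, semantics = semantics)
  }
  mask <- msr_mask(record, tracts)
  mean(mask[(start + 1L):end])
}

#' Window centred on an NEE heterotypic site cluster
#'
#' The window is centred on the midpoint of the minimal interval containing
#' the linked Twist and Dorsal hits and the Su(H) hit, then clipped to the
#' record.
#'
#' @param nee One NEE candidate row (from [find_nees()]).
#' @param record The `seq_record` the candidate lies on.
#' @param width Window width in bp (must be even; default 400).
#' @return List with `interval` (data frame) and `clipped` flag.
#' @export
center_window_on_cluster <- function(nee, record, width = 400L) {
  if (width %% 2L != 0L) stop("width must be even")
  lo <- min(nee$twist_start, nee$dorsal_start, nee$suh_start)
  hi <- max(nee$twist_end, nee$dorsal_end, nee$suh_end)
  mid <- (lo + hi) %/% 2L
  half <- width %/% 2L
  start <- max(0L, mid - half)
  end <- min(record$length, mid + half)
  list(interval = interval_df(record$id, start, end),
       clipped = (mid - half < 0L) || (mid + half > record$length))
}
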