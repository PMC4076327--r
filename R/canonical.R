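# Synthetic stand-ins for the canonical Neurogenic Ectoderm Enhancers.
# The real enhancer fragments are not redistributable, so these generators
# build sequences with the documented site architecture: one Su(H) site, one
# linked Twist-Dorsal pair at the locus-specific spacer length, a Snail site,
# MSR-filled spacers and flanks (Hawaiian-like fill for the "pure" NEEs,
# background-level fill for the Dpp-constrained vnd NEE, which additionally
# carries a Schnurri/Mad/Medea Silencer Element). Candidates are screened so
# the grammar occurs exactly once per sequence, as in the genuine enhancers.

# An MSR-biased segment: tandem tracts (units drawn mostly from the CA / CAR
# / AG families seen in embryonic enhancers) interleaved with background
# runs; `target` is the planted tract fraction of the segment.
msr_fill_segment <- function(len, target) {
  if (len <= 0L) return("")
  if (target <= 0) return(paste(random_bases(len), collapse = ""))
  mt <- 14; mb <- 10 # mean tract and background chunk lengths
  q <- target * mb / (mt * (1 - target) + target * mb)
  parts <- character(0)
  built <- 0L
  while (built < len) {
    if (stats::runif(1) < q) {
      r <- stats::runif(1)
      unit <- if (r < 0.40) "CA"
      else if (r < 0.50) "AG"
      else if (r < 0.65) sample(c("CAA", "CAG"), 1L)
      else paste(random_bases(sample(2:6, 1L)), collapse = "")
      chunk <- strrep(unit, sample(2:5, 1L))
    } else {
      chunk <- paste(random_bases(sample(5:15, 1L)), collapse = "")
    }
    parts <- c(parts, chunk)
    built <- built + nchar(chunk)
  }
  substr(paste(parts, collapse = ""), 1L, len)
}

#' Synthetic NEE stand-in with full site architecture
#'
#' Assembles a sequence of exactly `length` bp carrying, left to right: MSR
#' fill, a Snail site, the Twist:Da site, an MSR-filled spacer of exactly
#' `spacer_len` bp, the Dorsal core, more fill, the single Su(H) site, and
#' fill to the end (plus an SMMSE instance in the right flank when
#' `smmse = TRUE`). The assembly is rejected and resampled until the
#' sequence contains exactly one Su(H) site and exactly one NEE candidate,
#' at the planted spacer.
#'
#' @param id Record id.
#' @param length Total length in bp.
#' @param spacer_len Twist-Dorsal spacer in bp.
#' @param suh_offset Gap between the Dorsal site end and the Su(H) site in
#'   bp.
#' @param seed Mandatory integer seed.
#' @param msr_fill Planted tract fraction of the fill segments.
#' @param suh_strand Strand of the Su(H) instance.
#' @param smmse Plant an SMMSE instance.
#' @param species Species label for the record.
#' @param content_range Optional length-2 vector: the assembly is resampled
#'   until the MSR content of the 400 bp cluster-centred window falls inside
#'   this range, pinning the stand-in to the documented content regime.
#' @return A `seq_record`.
#' @export
make_nee_standin <- function(id, length = 600L, spacer_len, suh_offset = 45L,
                             seed, msr_fill = 0.45, suh_strand = "+",
                             smmse = FALSE, species = NA_character_,
                             content_range = NULL) {
  with_seed(seed, {
    for (try in seq_len(500L)) {
      snail <- instantiate_iupac("CARRTG")
      dorsal <- instantiate_iupac("GGAAABYCC")
      suh <- instantiate_iupac("YGTGRGAA")
      if (suh_strand == "-") suh <- revcomp(suh)
      core <- paste0(
        snail,
        msr_fill_segment(30L, msr_fill),
        "CACATGT",
        msr_fill_segment(spacer_len, msr_fill),
        dorsal,
        msr_fill_segment(suh_offset, msr_fill),
        suh)
      right_extra <- if (smmse) {
        paste0(msr_fill_segment(25L, msr_fill),
               instantiate_iupac("MYGGCGWCACACTGTCTGS"))
      } else {
        ""
      }
      core <- paste0(core, right_extra)
      room <- length - nchar(core)
      if (room < 0L) stop("length too small for the site architecture")
      left <- room %/% 2L
      s <- paste0(msr_fill_segment(left, msr_fill), core,
                  msr_fill_segment(room - left, msr_fill))
      rec <- seq_record(id, s, species = species)
      if (nrow(scan_motif(rec, "SuH", "both")) != 1L) next
      if (nrow(annotate_smmse(rec)) != (if (smmse) 1L else 0L)) next
      cand <- find_nees(rec)
      if (!(nrow(cand) == 1L && cand$spacer_len == spacer_len)) next
      if (!is.null(content_range)) {
        win <- center_window_on_cluster(cand[1L, ], rec, 400L)
        cont <- msr_content(rec, win$interval)
        if (cont < content_range[1] || cont > content_range[2]) next
      }
      return(rec)
    }
    stop("could not assemble a clean NEE stand-in")
  })
}

# Locus table for the canonical architecture: spacer lengths 14/10/5/8 at
# brk/rho/vn/vnd; the Su(H) site is on the bottom strand at vn; vnd carries
# an SMMSE and background-level MSR fill, the others Hawaiian-like fill.
.CANONICAL_NEES <- data.frame(
  locus = c("brk", "rho", "vn", "vnd"),
  spacer_len = c(14L, 10L, 5L, 8L),
  suh_offset = c(45L, 70L, 55L, 40L),
  suh_strand = c("+", "+", "-", "+"),
  smmse = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Synthetic canonical NEE set (picture-wing-like genome)
#'
#' Four 600 bp stand-ins at the canonical loci *brk*, *rho*, *vn*, *vnd*
#' with Twist-Dorsal spacers of 14, 10, 5 and 8 bp respectively; *vn*'s
#' Su(H) site is on the bottom strand and *vnd* carries an SMMSE with
#' background-level MSR fill (the other loci get Hawaiian-like fill).
#'
#' @param seed Mandatory integer seed.
#' @param msr_fill Fill fraction for the non-vnd ("pure") loci.
#' @param species Species label.
#' @return Named list of `seq_record` (names are loci).
#' @export
make_canonical_nee_standins <- function(seed, msr_fill = 0.45,
                                        species = "picture-wing-like") {
  tab <- .CANONICAL_NEES
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                          nrow(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    make_nee_standin(
      id = paste0(tab$locus[i], "_NEE"),
      length = 600L,
      spacer_len = tab$spacer_len[i],
      suh_offset = tab$suh_offset[i],
      seed = sub_seeds[i],
      msr_fill = if (tab$smmse[i]) 0.10 else msr_fill,
      suh_strand = tab$suh_strand[i],
      smmse = tab$smmse[i],
      species = species,
      content_range = if (tab$smmse[i]) c(0.28, 0.40) else c(0.45, 0.55))
  })
  names(out) <- tab$locus
  out
}

#' Synthetic cloned-fragment set (modified-mouthparts-like species)
#'
#' Stand-ins for the three cloned enhancer fragments, at the documented
#' fragment lengths: *rho* 626 bp, *vn* 513 bp, *vnd* ~500 bp. The *vnd*
#' fragment carries an SMMSE; *rho* and *vn* are "pure" NEEs with
#' Hawaiian-like MSR fill.
#'
#' @param seed Mandatory integer seed.
#' @param msr_fill Fill fraction for the pure loci.
#' @param species Species label.
#' @return Named list of `seq_record` (names are loci).
#' @export
make_cloned_fragment_standins <- function(seed, msr_fill = 0.45,
                                          species = "mouthparts-like") {
  spec <- data.frame(
    locus = c("rho", "vn", "vnd"),
    length = c(626L, 513L, 500L),
    spacer_len = c(10L, 5L, 8L),
    suh_offset = c(70L, 55L, 40L),
    suh_strand = c("+", "-", "+"),
    smmse = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                          nrow(spec)))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    make_nee_standin(
      id = paste0("mim_", spec$locus[i], "_NEE"),
      length = spec$length[i],
      spacer_len = spec$spacer_len[i],
      suh_offset = spec$suh_offset[i],
      seed = sub_seeds[i],
      msr_fill = if (spec$smmse[i]) 0.10 else msr_fill,
      suh_strand = spec$suh_strand[i],
      smmse = spec$smmse[i],
      species = species,
      content_range = if (spec$smmse[i]) c(0.28, 0.40) else c(0.45, 0.55))
  })
  names(out) <- spec$locus
  out
}
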