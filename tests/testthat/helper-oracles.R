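# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# plus-strand match starts of an IUPAC motif, by position-by-position
# character-class membership (sequence N never matches)
oracle_scan_plus <- function(seq, iupac) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- strsplit(iupac, "", fixed = TRUE)[[1]]
  L <- length(m)
  starts <- integer(0)
  for (i in seq_len(max(0L, length(s) - L + 1L))) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(s[i + j - 1L] %in% .ORACLE_IUPAC[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i - 1L) # 0-based
  }
  starts
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

# 0-based positions covered by some tandem doubling seed (i, u):
# seq[i, i+u) == seq[i+u, i+2u), no N inside, u in [unit_min, unit_max]
oracle_tandem_cover <- function(seq, unit_min = 2L, unit_max = 50L) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(s)
  covered <- logical(L)
  if (L < 2L * unit_min) return(integer(0))
  for (u in unit_min:min(unit_max, L %/% 2L)) {
    for (i in 0:(L - 2L * u)) {
      left <- s[(i + 1L):(i + u)]
      right <- s[(i + u + 1L):(i + 2L * u)]
      if (!any(left == "N") && !any(right == "N") && all(left == right)) {
        covered[(i + 1L):(i + 2L * u)] <- TRUE
      }
    }
  }
  which(covered) - 1L
}

# two-sided Fisher p by direct hypergeometric summation: sum of P(tables)
# with probability <= observed, fixed margins, with the conventional 1e-7
# relative tie tolerance
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b      # test size
  n <- c + d      # control size
  k <- a + c      # total with-feature
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alph, n, replace = TRUE, prob = prob), collapse = "")
}

# all strings over {A, C} of lengths len_min..len_max
ac_strings <- function(len_min, len_max) {
  out <- character(0)
  for (L in len_min:len_max) {
    grid <- do.call(expand.grid, rep(list(c("A", "C")), L))
    out <- c(out, do.call(paste0, grid))
  }
  out
}
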