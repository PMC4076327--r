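---
title: "Microsatellite-repeat footprinting of embryonic enhancers: models and methods"
author: "msrfoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite-repeat footprinting of embryonic enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrfoot)
```

## The scientific problem

Early-embryo enhancers in *Drosophila* are dense arrangements of binding
sites for a small set of transcription factors. The Neurogenic Ectoderm
Enhancers (NEEs) are the canonical example: each carries a Twist:Daughterless
E-box (`CACATGT`) linked to a Dorsal site (core `GGAAABYCC`) by a short
spacer, with a Su(H) site (`YGTGRGAA`) nearby, plus Snail and Zelda sites.
The spacer length between the linked Twist and Dorsal sites tunes the
enhancer's response to the Dorsal morphogen gradient, so spacer-changing
mutations are functional variants.

Replication slippage on tandem microsatellite repeats (MSR; here, two or more
direct head-to-tail copies of a 2-50 bp unit) is the dominant source of such
indels. In lineages under sustained pressure to retune embryonic enhancers,
the inter-site spacer DNA becomes saturated with MSR while the binding sites
themselves persist — the repeats "footprint" the functional sites the way
divergence does in phylogenetic footprinting. This package implements the
computational side of that analysis as a reusable pipeline:

1. **motif scanning** — exact IUPAC-degenerate matching on both strands;
2. **NEE discovery** — linked Twist-Dorsal pairs (spacer 0-41 bp) with a
   Su(H) site within 300 bp;
3. **MSR detection** — exhaustive tandem-repeat finding, per-base masks and
   windowed MSR content;
4. **block extraction** — genome-wide Su(H)- or Zelda-anchored blocks with
   flanks and single-linkage site clusters;
5. **homology search** — a word-seeded local aligner with blastn-style
   scoring (+5/-4, gap 8+6L, word size 9) and Karlin-Altschul E-values,
   with reciprocal-best-hit filtering;
6. **enrichment testing** — Zelda-positive test set vs depleted control set,
   presence/absence of MSR classes, Fisher and permutation p-values;
7. **simulation** — background genomes, planted architectures, slippage
   evolution and diverged ortholog pairs with known ground truth.

## Tandem-repeat semantics

The field's informal definition of an MSR tract is a regular expression,
`(.{2,50})\1`: some unit of 2-50 bp immediately repeated. A single
backtracking pass of that pattern is not a stable mathematical object — its
output depends on the engine's traversal order, and a leftmost-greedy pass
misses shifted copies (on `ACGTACGTA` it covers only the first 8 bases,
although the last 8 also form a doubled unit). `find_tandem_repeats()`
therefore uses **exhaustive semantics** by default: every position `i` and
unit length `u` with `seq[i, i+u) == seq[i+u, i+2u)` seeds a tract, seeds are
extended rightward by whole unit copies, and every maximal (interval, unit
length) is reported. The original single-pass behaviour is retained as the
`regex_single_pass` dialect; its coverage is provably a subset of the
exhaustive coverage, and the suite checks exhaustive coverage against a
brute-force doubling oracle on every `{A,C}` string up to length 12.

Two consequences of the definition are worth knowing. First, partial
trailing copies never extend a tract (intervals contain whole copies only,
matching the regex). Second, the same repeat locus is reported at several
unit lengths — a `(CA)4` run is also a `(CACA)2` run — which is correct for
coverage but would over-count "repeat loci"; consumers that need loci (the
slippage simulator) first reduce to primitive units (units that are not
themselves repeats) and collapse phase rotations.

`N` bases never match any motif letter and always break repeat tracts:
assembly gaps must not create hits. IUPAC ambiguity codes other than `N` in
*input sequences* are normalized to `N` on reading.

## The MSR content statistic

`msr_content()` is the fraction of positions in a window covered by at least
one tract, conventionally over a 400 bp window centred on the NEE's
heterotypic site cluster (`center_window_on_cluster()` uses the midpoint of
the minimal interval containing the Twist, Dorsal and Su(H) hits; the window
is clipped at sequence edges and flagged). Under this liberal definition
random uniform DNA already carries substantial coverage (~28-35% in 400 bp),
which is why the statistic is read comparatively: Hawaiian "pure" NEEs sit
around 43-57%, non-Hawaiian ones around 32-38%.

## NEE grammar discovery

`find_linked_pairs()` enumerates **all** placements of a Twist:Da match and
a Dorsal-core match separated by 0-41 intervening bases, on both strands and
in either order (the Dorsal site is functional in any orientation). The
41 bp bound follows the machine-readable search pattern
(`CACATGT.{0,41}GGAAA[^A][CT]CC`); a `grep` dialect reproduces the
single-pass shell-script behaviour and is a subset of the enumeration.
`find_nees()` promotes a pair to a candidate when a Su(H) site's nearest
edge lies within 300 bp of the pair span (nearest-edge distance, signed by
side; the reference point is a documented choice — the text does not fix
edge vs midpoint). Both strands are always scanned; a palindromic interval
is reported once per strand.

## Block extraction dialects

Genome-wide analyses work on anchor blocks: each Su(H) hit, or single-linkage
cluster of hits with successive gaps below a merge threshold, plus fixed
flanks, clipped at contig edges (clipped blocks are kept and flagged
truncated). The source descriptions of the flank are mutually inconsistent
(270 bp in one place; 292 bp "because (292 x 2) + 8 = 600" in another, whose
own arithmetic gives 592), so the flank is an explicit parameter with three
documented dialects — 270, 292, and 296 (the value that actually makes
single-site blocks 600 bp, consistent with anchoring the site at position
300 in the figures). The merge threshold defaults to twice the flank, with
the fixed 540 bp dialect also available. Zelda blocks are plus/minus 300 bp
around each perfect `CAGGTAR` site (607 bp single-site blocks). Because the
genome assemblies behind the published census totals cannot be
redistributed with the package, the census machinery is validated on
synthetic multi-contig genomes against a single-linkage oracle under all
three dialects rather than against the printed totals.

## The homology aligner and its statistics

`align_pair()` re-implements the "regulatory blastn" search used to find
conserved blocks between species, with the published parameter set as
defaults: reward +5, penalty -4, gap open 8, gap extend 6 (a gap of length
L costs `8 + 6L`, the NCBI flag convention), word size 9, final x-drop 90,
best-hit overhang 0.25 and score edge 0.1. Each pair is processed in two
stages per subject strand: exact 9-mer seeds (one per diagonal) are extended
ungapped under the x-drop rule; if the best extension reaches the gapped
trigger (default 50), a full affine-gap local DP is run with traceback. The
design choice of an exact DP for the gapped stage (rather than a banded
x-drop extension) means reported scores equal the Smith-Waterman optimum
whenever a seed exists — the property the suite checks against an
independent dynamic-programming oracle — at negligible extra cost for
block-sized sequences. Edit strings rescore exactly under the scheme.

E-values use ungapped Karlin-Altschul statistics, `E = K m n exp(-lambda S)`.
`lambda` solves `sum p_i p_j exp(lambda s_ij) = 1` by bracketed root-finding
(tolerance 1e-9); `K` uses the standard ungapped lattice formula
`K = d lambda e^(-2 sigma) / (H (1 - e^(-lambda d)))` with `d` the lattice
span of the score support and `sigma` a Spitzer-type sum over k-fold
convolutions of the score distribution. For +5/-4 at uniform base
frequencies this gives `lambda = 0.1915`, `K = 0.176`, `H = 0.357`. Gapped
statistics are deliberately approximated by the ungapped values, and no
effective-length correction is applied by default; E-values are therefore
not bit-identical to NCBI's gapped tables, and published conserved-block
counts (~3,400 at E < 1e-15; 3,975 at E < 1e-40) are treated as approximate
calibration context, not reproduction targets. What is verified instead is
operational: on planted ortholog benchmarks (600 bp blocks, 25% divergence,
short indels) reciprocal-best-hit assignment at E < 1e-15 attains at least
95% recall and precision.

## Partition and enrichment

`partition_blocks()` reproduces the embryonic/non-embryonic split: test
blocks carry at least one perfect Zelda site (`CAGGTAR`, both strands);
control blocks carry no hit to any Zelda-like depletion motif (`CAGGTA`,
`CAGGCAR`, `TAGGTAR`) and at most one relaxed Su(H) match (`GTGNGAA` — the
7-mer core; the longer printed strings only mark the site's extent). Blocks
in neither set are tracked as dropped, never discarded silently; the three
sets always partition the input.

De-novo EM motif discovery is intentionally out of scope. The biological
conclusions concern specific repeat families, so `enrichment_test()` works
directly on presence/absence of pre-specified MSR classes — CA-dinucleotide
(units CA/TG in any phase), CAR-trinucleotide (CAA/CAG and complements),
AG-dinucleotide, and T-runs — at a minimum tandem copy number (default 3;
T-runs default to a minimum run of 5). The 2x2 table is tested two-sidedly
with Fisher's exact test (`stats::fisher.test`, which the suite checks to
1e-12 against an independent hypergeometric summation) plus a seeded
label-permutation p-value; odds ratios use a Haldane 0.5 correction on zero
cells. `evalue_distribution_check()` guards the design against a
conservation confound: a rank-based (Wilcoxon) comparison of log10 E-values
between the sets, reported as the probability that a random test block is
more conserved than a random control block (0.5 under no shift).

One statistical subtlety is documented rather than hidden: Fisher's exact
test is conservative, so its true size at alpha = 0.05 under the package's
null benchmark is about 0.036-0.040, not 0.050. The calibration check in
the suite therefore asserts the 3-7% band on the *exactly enumerated*
rejection rate (binomial-weighted sum over all tables at the observed
presence probability) and requires the 200-replicate Monte Carlo rate to be
consistent with that exact rate, rather than gambling the band on a single
noisy rate estimate.

## The slippage simulator

`evolve_slippage()` implements the mutational mechanism the analysis
invokes. Per generation, tandem tracts are located, reduced to primitive
units and phase-deduplicated (one slippage locus per repeat run); the
expected event count is `per_site_rate` per locus (default 0.05); a locus is
chosen with probability proportional to `copies^length_exponent` (default
exponent 1 — instability grows with repeat length); and an event inserts one
whole unit copy with probability `p_expand` (default 0.6) or removes one.
Contractions at the minimum copy number are aborted: a two-copy tract that
lost a unit would cease to be a repeat, so the misaligned intermediate has
no shorter register to slip into; this also makes the expansion bias
effective in raising windowed MSR content, the qualitative behaviour the
simulator exists to emulate. Point substitutions (optional) avoid protected
intervals, emulating binding sites that persist under purifying selection
while the spacers fill with repeats; protected intervals are shifted along
with surviving indels. All generators take a mandatory seed, use one
private RNG stream per call, and never touch the caller's RNG state.

Defaults were chosen once, on qualitative grounds: 0.05 events per locus
per generation with a 60/40 expansion bias over 200 generations roughly
doubles a 600 bp sequence's repeat load — enough to move a sequence from
background-level (~30%) toward Hawaiian-level (~50%) windowed content — and
they were not revisited afterwards.

## Synthetic stand-ins for the study sequences

The enhancer fragments and genome assemblies analysed in the source study
are not redistributable, so every fixture here is generated:

- `make_canonical_nee_standins()` builds four 600 bp enhancers at the
  canonical loci with the documented architecture: Twist-Dorsal spacers of
  14 (*brk*), 10 (*rho*), 5 (*vn*) and 8 bp (*vnd*); a single Su(H) site
  (bottom strand at *vn*); a Snail site; an SMMSE (19-mer
  `MYGGCGWCACACTGTCTGS`) only at *vnd*. Spacers and flanks are filled with
  an MSR-biased segment generator (tracts drawn mostly from the CA/CAR/AG
  families, interleaved with background runs).
- `make_cloned_fragment_standins()` does the same at the documented cloned
  fragment lengths (626, 513, ~500 bp).

Assemblies are rejection-sampled until the grammar occurs exactly once and —
for the "pure" (non-SMMSE) loci — the 400 bp window content lies in the
documented Hawaiian band (45-55% is targeted, inside the published 43-57%);
*vnd* stand-ins are pinned to the background-like 28-40% band. These bands
are study conditions, not free parameters. Because the generator screens
with the same detectors the pipeline uses, tests on stand-ins demonstrate
**consistency** (the pipeline reports the architecture that was planted),
not discovery power; discovery is tested separately by planting experiments
with independent ground truth (500 plantings across the full spacer range
recover every spacer exactly) and by the brute-force oracles. The stand-ins
also do not emulate real enhancer features beyond the planted grammar and
repeat load — no binding-site turnover, no phylogenetic correlation, no
base-composition skew — so passing tests say nothing about, e.g., motif
false-positive rates in real heterogeneous genomes.

## Reproducibility and numerical choices

- Coordinates are 0-based half-open everywhere internally; BED output
  inherits this convention; only prose reports are 1-based.
- All stochastic functions require a seed; identical (parameters, seed)
  give byte-identical outputs, including the pipeline runners' TSV/JSON
  output files.
- `estimate_karlin()` rejects schemes with non-negative expected score;
  root-finding tolerance is 1e-12 on a bracket, reported to better than
  1e-9.
- Alignment tie-breaks are deterministic (score, then subject id, then
  subject start); the DP prefers diagonal moves on ties.
- Degenerate inputs: empty FASTA files, duplicate ids and illegal
  characters are errors with positions; sequences shorter than the word
  size yield empty alignment results; empty block sets give all-zero
  summaries; an empty genome terminates the pipeline runners cleanly.

Problem sizes in the shipped tests and acceptance script (600 bp blocks,
40-pair ortholog benchmarks, 20 x 20 kb synthetic genomes, 200-replicate
calibrations) were chosen as the smallest sizes at which the statistical
claims are individually well-powered; all scale linearly if increased.

## Known limitations

- E-values are ungapped-statistics approximations; absolute conserved-block
  counts from gapped NCBI searches are not reproducible bit-for-bit.
- The aligner reports one optimal local alignment per subject strand per
  pair (plus best-hit culling), not a full HSP list.
- The slippage model is mechanistic but minimal: no unit-composition bias
  in mutation rates, no interruption-dependent stabilization, no point
  mutations inside tracts unless enabled globally.
- Exhaustive tandem detection is O(L x unit_max) per sequence and is
  intended for enhancer- and contig-scale sequences, not whole mammalian
  genomes in one string.
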