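Package: msrfoot
Title: Microsatellite-Repeat Footprinting of Embryonic Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects direct tandem microsatellite repeats (MSR) and quantifies
    windowed MSR content in regulatory DNA; discovers Neurogenic Ectoderm
    Enhancer (NEE) candidates as linked Twist-Dorsal motif pairs with a nearby
    Su(H) site; extracts genome-wide anchor-site blocks around Su(H) or Zelda
    motifs; finds cross-species homologous blocks with a word-seeded local
    aligner using blastn-style scoring and Karlin-Altschul E-values, including
    reciprocal-best-hit filtering; partitions conserved blocks into embryonic
    (Zelda-positive) and depleted control sets and tests MSR motif-class
    enrichment between them; and simulates background genomes, planted motif
    architectures, ortholog pairs and replication-slippage MSR evolution so the
    whole pipeline can be exercised on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
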