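Package: phasr
Title: Discovery of Phased Small Interfering RNA (PHAS) Loci from Plant
    Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting phased secondary siRNA
    (phasiRNA) producing loci from plant small RNA sequencing libraries.
    Implements adaptor trimming, read collapsing, rRNA filtering and
    exact-match genome placement; a phase-register sliding-window scan
    with a hypergeometric phasing P-value for 21-nt loci and a
    log-scale phasing score for 24-nt loci; genomic classification of
    loci against gene models (exon, intron, exon-intron junction,
    intergenic) with RNA-seq-based intron-retention assessment;
    prediction of miRNA/siRNA triggers (one-hit 22-nt and two-hit
    models) and phasiRNA targets under a plant-specific duplex penalty
    scheme with degradome validation; differential phasiRNA production
    between libraries; and a seeded synthetic-data generator that
    plants PHAS loci with full truth tables so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
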