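Package: ampliseqr
Title: Multiplexed Dual-Barcode Amplicon Sequencing Analysis for
    Insecticide Resistance Surveillance
Version: 0.1.0
Authors@R: person("LSHTM", "PathogenSeq", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for targeted amplicon deep sequencing of pooled,
    internally barcoded PCR products, as used to screen mosquito
    populations for insecticide resistance target-site mutations.
    Provides a panel/sample-sheet data model with IUPAC-aware primer
    matching, a paired-end pool simulator with configurable sequencing
    error and barcode mistagging, dual 6bp-barcode demultiplexing with
    mistag removal, glocal alignment to amplicon reference inserts,
    quality-filtered pileup SNP/indel calling with allele-ratio diploid
    genotyping, cohort-level variant retention filters and consequence
    annotation, and population-genetic reporting (allele frequencies,
    Hardy-Weinberg equilibrium tests, Tajima's D, genotype concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
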