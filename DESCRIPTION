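Package: plastidmarker
Title: Comparative Plastome Analysis and Species-Diagnostic Barcode Marker Discovery
Version: 0.1.0
Authors@R:
    person("Plastid", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative chloroplast-genome analysis and the
    design of species-diagnostic DNA barcode markers. Detects the inverted
    repeat pair and derives the quadripartite (LSC/IRb/SSC/IRa) partition with
    per-region length and GC statistics; scans perfect microsatellites (SSRs)
    with MISA-style unit-count thresholds and assigns genomic region and genic
    context; profiles sliding-window sequence identity across multiple
    alignments to rank variable regions; calls species-diagnostic substitutions
    and indels from labeled alignments and designs conserved-flank primer
    pairs; and builds neighbor-joining trees from Poisson-corrected p-distances
    with bootstrap supports. Includes a fully seeded synthetic-plastome
    generator with truth tables for property-based validation, and a
    subcommand-style command line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
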