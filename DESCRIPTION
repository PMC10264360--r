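Package: holosim
Title: Coarse-Grained Polymer Modelling and Annotation of Megabase-Scale
    Holocentromeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the condensation of a holocentric chromatid whose
    centromere is built from a few megabase-scale satellite-array units, as
    found in the lilioid plant Chionographis japonica. Provides a
    beads-on-a-string chromatin fiber with a selective attractive-repulsive
    potential between centromeric nucleosomes, SMC-like loop extruders on a
    1D lattice that are excluded from centromere units and anchor at their
    borders, and an overdamped Langevin engine with spherical nuclear
    confinement for the interphase phase. Companion tooling quantifies unit
    condensation, chromocenter clustering and line-like holocentromere
    formation, re-implements the CENH3 ChIP domain to centromere-unit
    calling procedure (dual-caller intersection, sub-500-kb gap merging,
    sub-1-kb filtering) with summary statistics on BED-style intervals,
    scans satellite monomers for dyad symmetries and cross-monomer hairpin
    arms, and generates seeded synthetic genomes, caller tracks, genes and
    satellite monomers so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
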