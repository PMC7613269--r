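Package: capture3C
Title: Processing and Simulation of Capture-C Family Chromosome Conformation Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design and analysis of viewpoint-based chromosome
    conformation capture (3C) experiments of the Capture-C family, covering
    disperse single-fragment viewpoints (Capture-C), multi-way interaction
    viewpoints on short fragments (Tri-C) and contiguously tiled regions
    (Tiled-C). Provides restriction-fragment maps for 4-base cutters,
    capture-probe design and filtering, qPCR-based digestion-efficiency QC,
    in-silico digestion of chimeric paired-end reads, slice alignment and
    viewpoint annotation, coordinate-based PCR-duplicate removal, per-viewpoint
    reporter quantification with cis normalisation, binned contact matrices
    with iterative correction, and a seeded read simulator with full ground
    truth for closed-loop validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
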