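Package: isomiRscope
Title: Differential Expression, isomiR Windows and Novel Arm Detection
    Along microRNA Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Secondary analysis of human small-RNA sequencing data aligned
    with miRDeep2. Builds per-base read-coverage matrices along miRNA
    hairpin precursors from arf alignments and miRBase annotation,
    normalizes to reads per million, and tests case/control differences at
    precursor, mature-arm, arm-ratio and single-base resolution. Detects
    genome-templated isomiR end extensions by window coverage outside
    annotated arm ends, calls candidate unannotated mature arms on
    single-arm precursors, aggregates anonymized findings across studies,
    and renders Manhattan, per-base, read-distribution and pileup views
    with tab-delimited twins. Includes a seeded negative-binomial study
    simulator with a truth table for parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'aggregation.R'
    'annotation.R'
    'arf.R'
    'coverage.R'
    'differential.R'
    'isoforms.R'
    'isomiRscope-package.R'
    'pipeline.R'
    'reporting.R'
    'simulate.R'
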