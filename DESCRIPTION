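Package: snmcpipe
Title: Simulation and Analysis Pipeline for Single-Cell Bisulfite
    Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale computational stack for single-nucleus
    methylome (snmC-seq2-style) libraries: simulation of post-bisulfite
    adapter-tagged paired-end reads with realistic artifact chemistry
    (in-line barcodes, low-complexity Adaptase tails, adapter dimers,
    PCR duplicates, unmethylated lambda spike-in), demultiplexing and
    trimming with model-based tail detection, three-letter bisulfite
    alignment, per-cytosine methylation calling into allc-style tables,
    per-cell quality control including Good-Toulmin library-complexity
    extrapolation and coverage-uniformity statistics, and methylome
    clustering on 100 kb bins with marker-gene cell-type annotation.
    Every stage is verifiable against simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
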