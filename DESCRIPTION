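Package: methentropy
Title: Cell-to-Cell DNA Methylation Heterogeneity from Read-Level
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates cell-to-cell heterogeneity in DNA methylation from
    read-level bisulfite sequencing (BS-seq) data. CpG sites are enumerated
    from a reference genome, grouped into segments of four consecutive
    sites, and the methylation patterns observed on individual reads are
    tallied per segment. Normalized Shannon entropy and a Gini index over
    the pattern distribution quantify heterogeneity, alongside the
    conventional methylation level. A frequency-based filter cascade
    removes error-derived rare patterns so that bulk estimates match a
    single-cell gold standard built by per-cell epiallele calling with a
    top-two pattern frequency-ratio test. Includes permutation tests and
    bootstrap standard errors, per-gene region aggregation, genome-browser
    track export, a read-level cohort simulator with configurable
    technical-error models, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    grDevices,
    IRanges,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
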