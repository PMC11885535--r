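Package: screendiff
Title: Differential Essentiality Analysis for Pooled CRISPR Screens
    Across Growth Environments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of pooled CRISPR/Cas9 loss-of-function screens run in
    parallel growth environments (cell culture versus xenograft), built to
    detect genes whose knockout effect differs, or even reverses sign,
    between environments. Provides inline-barcode demultiplexing and
    zero-mismatch protospacer counting from FASTQ reads, total-read
    normalisation, paired log2 fold changes against initial library
    samples, gene-level aggregation, non-targeting-control-centred
    z-scores, and a per-gene in vitro versus in vivo Welch t-test with
    Benjamini-Hochberg false discovery rates and hit classification.
    Includes a ground-truthed negative-binomial screen simulator with an
    engraftment bottleneck for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Sequencing,
    StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
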