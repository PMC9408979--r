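Package: teacr
Title: Transposable-Element-Derived Accessible Chromatin Region Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterising accessible chromatin regions (ACRs)
    that arise from transposable elements (TEs) in plant genomes. Classifies
    ATAC-seq peaks by TE coverage and position relative to genes, calls
    tissue-specific peaks by Shannon entropy of per-tissue accessibility,
    profiles DNA methylation and ATAC signal around TEs and peaks, scans
    wild versus cultivated genotype panels for domestication sweeps using
    windowed nucleotide diversity ratios, and relates TE-derived peaks near
    transcription start sites to the sequence divergence (Nei-Gojobori
    Ka/Ks) of duplicated gene pairs. Includes a synthetic mini-genome
    simulator so every analysis stage can be exercised end to end without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
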