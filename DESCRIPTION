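Package: gipool
Title: Genetic Interaction Scoring from Pooled Double-Mutant Barcode Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping condition-dependent genetic interactions from
    pooled yeast double-mutant fitness screens that read out strain abundance
    through fused barcode sequencing. Covers the full analysis path: a
    forward simulator of pooled exponential growth with ground-truth epistasis,
    mismatch-tolerant demultiplexing and fused-barcode counting from paired
    FASTQ reads, strain- and pair-level quality control (heterozygous-diploid
    coverage, genetic linkage, replicate profile correlation), multiplicative
    genetic-interaction scores with delta-method error propagation and
    empirical-null p-values, inverse-variance gene-level aggregation with
    Storey q-values, and differential (condition-dependent) interaction calls
    with condition clustering.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
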