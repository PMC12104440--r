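Package: screenfit
Title: Scoring and Quality Control for Pooled CRISPR Resistance Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-arm (control versus drug) pooled
    CRISPR knockout resistance screens. Counts guide spacers in sequencing
    reads, normalizes guide abundances, computes per-guide log2 fold
    changes and their z-score transform, aggregates them into a per-gene
    CRISPR fitness score, runs essentiality ROC quality control, classifies
    genes on a nine-square selection plot, and ranks resensitizer and
    resistance-enhancer hits against a non-targeting-control null. A
    companion simulator generates guide libraries, negative-binomial screen
    counts with known selection coefficients, synthetic FASTQ reads, and
    paired differential-accessibility/expression tables with a tunable
    concordance fraction, so every step can be validated by parameter
    recovery. Also includes the chromatin-accessibility concordance step:
    differential peak classification, promoter/enhancer peak-to-gene
    assignment, DE-gene concordance fractions, and TSS signal profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
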