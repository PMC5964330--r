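Package: chromstates
Title: Promoter Chromatin States from Low-Input ChIP-Seq Coupled to Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based calling of H3K4me3, H3K27me3 and H3K9me3 marks in
    20-kb promoter regions centered on transcription start sites, combinatorial
    classification of each gene into one of eight chromatin states per cell
    type, enrichment of gene sets in chromatin-state transitions between cell
    types (odds ratios, Fisher's exact test, Benjamini-Hochberg FDR), and
    expression-side integration: RPKM, silent-gene classification, per-state
    expression tests, single-nucleus QC by median absolute deviation, and
    highly-variable-gene variance decomposition. Includes a negative-binomial
    simulator that generates ChIP window counts, coverage profiles, expression
    tables and regulated gene sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
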