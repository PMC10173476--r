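Package: crossploidy
Title: Cross-Ploidy Transcriptome Comparison for Synthetic Allohexaploid
    Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing transcriptomes across ploidy levels in
    synthetic allohexaploid wheat (AABBDD) and its tetraploid (AABB) and
    diploid (DD) parents. Implements subgenome-mismatch correction of
    parental read counts, split-by-subgenome TMM normalization within
    genotype-consistent groups, negative-binomial differential expression
    with fold-change and FDR thresholds, midparent-value testing of
    transposable-element family transcription, in-silico karyotyping from
    windowed expression ratios, homoeolog expression bias classification
    of triads by eigen distance on the expression simplex, and
    hypergeometric/binomial statistics for differentially expressed gene
    set overlaps. Includes a seeded negative-binomial simulator of
    parent/synthetic count tables with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
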