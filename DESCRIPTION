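Package: cfmedip
Title: Differential Methylation Analysis of cfMeDIP-seq Bin Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide differential methylation analysis for cell-free
    methylated DNA immunoprecipitation sequencing (cfMeDIP-seq) of plasma
    samples. Provides 300-bp genome binning, leukocyte-background and
    blacklist filtering of bin counts, a negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    CpG-context / gene-feature / repeat annotation of differentially
    methylated regions, permutation-based genomic enrichment Z-scores,
    hypergeometric gene-set over-representation, droplet digital PCR
    sample quality control, exploratory transforms (variance flattening,
    SVD batch checks, k-means staging, heatmap matrices), and a fully
    seeded synthetic-cohort generator with ground truth for validating
    every stage without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
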