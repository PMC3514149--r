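Package: blastomics
Title: Differential Expression and Promoter Analysis for Two-Lineage
    Blastocyst Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparing the transcriptomes of the
    two cell lineages of the mammalian blastocyst (inner cell mass versus
    trophectoderm) from gene-level read counts.  Implements
    negative-binomial differential expression with median-of-ratios
    normalization, a locally regressed mean-variance trend and an exact
    conditional count-split test with dual significance cut-offs (adjusted
    P and minimum fold change); sum-of-squares guided k-means clustering
    of significant genes; promoter CpG-island classification by the
    observed/expected CpG ratio in a TSS-centered window; position weight
    matrix scanning of promoters with hypergeometric transcription-factor
    binding-site enrichment and generic over-representation analysis; and
    delta-delta-Ct qPCR quantification against a multi-gene reference.  A
    synthetic-data module generates counts, promoters and Ct tables with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
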