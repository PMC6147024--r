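Package: methfrag
Title: Fragment-Based RRBS Differential Methylation and Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of reduced representation bisulfite sequencing (RRBS)
    data at the MspI-fragment level: in-silico CCGG digestion of a reference
    genome, ingestion of per-CpG bisulfite methylation calls, coverage-
    standardised fragment quantification, genomic-element and repeat-family
    stratification of methylation, F-test calling of differentially
    methylated fragments with false discovery rate control, two-group
    differential expression on FPKM matrices, and integration of
    differential methylation with differential expression through promoter,
    gene-body and enhancer context, including Spearman correlograms of
    epigenetic regulator genes against global methylation. A synthetic-data
    generator produces genomes, annotations, beta-binomial bisulfite counts
    and coupled expression matrices with known ground truth so that every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
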