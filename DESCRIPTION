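Package: lncmarks
Title: Positional Classification of Plant lncRNAs and Their Overlap with
    Epigenetic Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for relating long noncoding RNAs
    (lncRNAs) to the plant epigenome. Transcripts assembled from RNA-seq are
    classified by genomic position into long intergenic noncoding RNAs
    (lincRNAs), natural antisense transcripts (NATs), intronic noncoding
    RNAs (incRNAs) and putative mRNAs; each class is then quantified for
    overlap with inverted repeat regions, 24-nt siRNA loci, cytosine-context
    DNA methylation (CG/CHG/CHH) and H3K27me3 domains. The package builds
    metagene profiles over feature sets, runs stratified expression
    comparisons, chains tabular BLAST HSPs into homology coverage across
    related genomes, performs hypergeometric GO enrichment with FDR
    control, and ships a fully parameterised synthetic-data generator with
    a ground-truth manifest so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
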