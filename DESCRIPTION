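Package: lociqtl
Title: Gene and QTL Annotation, Comparison and Enrichment for Candidate Loci in Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates candidate genomic loci (GWAS markers, windows, CNVs,
    runs of homozygosity) with genes from Ensembl-style GTF files and with
    previously reported quantitative trait loci (QTLs) from Animal-QTLdb-style
    GFF files, compares the annotations across grouping factors such as
    studies, breeds or models, and tests QTL over-representation with an
    upper-tail hypergeometric enrichment model computed in log space.
    Includes plot builders (overlap heat maps, QTL composition charts,
    enrichment bubble plots, chord diagrams), a deterministic synthetic-data
    generator for fully reproducible testing, and a command-line interface.
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
    grDevices,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    circlize,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
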