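Package: ampliko
Title: Amplicon Genotyping and Stop-Codon Guide Design for CRISPR
    Knockout Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and genotyping CRISPR gene-ablation
    experiments in mammalian embryos. Covers cytosine-base-editor guide
    design that installs premature stop codons (with per-isoform
    truncation and epitope-retention metrics), Cas9 nuclease guide
    annotation, amplicon deep-sequencing allele calling restricted to
    the CRISPR editing region, frame-arithmetic classification of
    alleles and mosaic embryo genotypes (wild type, in-frame,
    heterozygous, knockout), cohort editing-efficiency summaries with
    proportion tests, and a seeded synthetic-data generator that
    emulates mosaic embryo cohorts and error-bearing amplicon reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
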