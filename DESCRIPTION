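Package: digitag
Title: Digital Genotyping with Methylation-Sensitive Restriction Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for restriction-enzyme-targeted
    reduced-representation genotyping (digital genotyping, DG) of large,
    repeat-rich plant genomes. Models a nested, methylation-sensitive
    enzyme set (FseI, NgoMIV, HpaII plus MseI), digests reference genomes
    in silico under a methylation mask, classifies tag uniqueness,
    demultiplexes and filters barcoded single-end reads, discovers
    SNP/INDEL markers between parental inbreds, calls genotypes from
    allele read depths under depth-ratio policies, builds recombinant
    inbred line genetic maps with the Kosambi function, flags genome
    misassemblies, places supercontigs, segments shared haplotype blocks,
    and quantifies GC- and template-length-driven depth bias. Ships a
    read simulator that emulates these biases so every stage is testable
    against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    BiocGenerics,
    IRanges,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
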