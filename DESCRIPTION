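Package: nrpoly
Title: Nuclear Ribosomal DNA Polymorphism Profiling and ITS-CAPS Markers for Mulberry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intragenomic polymorphism of the nuclear
    ribosomal DNA (nrDNA) repeat unit in mulberry (Morus L.). Provides a
    region-aware coordinate model of the 5814 bp 18S-ITS1-5.8S-ITS2-26S
    unit, GATK-style hard filtering and homogeneous/heterogeneous
    classification of SNP and InDel calls, per-species per-region variant
    tallies, conversion of SNP genotypes into IUPAC ambiguity-coded
    haplotype sequences with exact-match deduplication, a neighbor-joining
    clustering of haplotype groups, regular-expression read counting for a
    13/16 bp ITS1 insertion, and an in-silico ITS-CAPS assay (primer-based
    amplicon extraction, BstEII/MstI digestion, and banding-pattern species
    diagnosis). A seeded synthetic-cohort generator emulates a 542-accession
    study so the whole pipeline is testable end to end without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
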