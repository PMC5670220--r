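Package: mutproc
Title: Mutational Signatures, Rearrangement Signatures, Clonality and
    Molecular Timing for Cancer Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse somatic mutation catalogs from tumor whole
    genomes: conversion of SNV calls into the 96 trinucleotide substitution
    categories, exposure fitting of known mutational signatures by
    non-negative least squares with a minimum-contribution discard rule,
    de novo signature extraction by non-negative matrix factorization,
    per-mutation and per-gene signature attribution, classification of
    structural rearrangements into 38 type/size/clustering categories and
    rearrangement-signature extraction, cancer cell fraction and clonality
    calls from read counts, purity and allele-specific copy number,
    molecular timing of chromosome duplications from duplicated versus
    non-duplicated mutation counts, replication-timing and
    transcription-associated mutation rate and strand-asymmetry analyses,
    and a fully seeded synthetic-tumor generator providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
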