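Package: palinsig
Title: Palindromic Core-Motif Mutation Signatures in Cancer Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and analysis of non-coding somatic mutation hotspots at
    short core motifs (such as TGAACA or AGATCA) flanked by perfect palindromic
    arms, the pattern characteristic of APOBEC-driven hairpin-loop mutagenesis
    in bladder cancer. Provides a reference-genome scanner for core motifs with
    maximal inverted-repeat arms (genome-wide and variant-window modes, with
    homopolymer and soft-masked-repeat filters), a cohort mutation-matrix model
    with per-locus frequencies and mutation-burden signature groups,
    contingency statistics with an explicit chi-square / Yates / Fisher
    selection rule plus rank-based group tests, pyrimidine-normalized
    trinucleotide context classification with APOBEC (SBS2) compatibility
    calls, qPCR delta-Ct relative expression quantification, and a fully
    seeded synthetic-data generator (genomes with implanted loci, correlated
    cohort mutation matrices, covariates, and Ct tables) with ground-truth
    records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
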