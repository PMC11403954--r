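Package: paleofix
Title: Timing of Derived-Allele Fixation in Polar Bears from Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for deciding which derived alleles in a panel of
    candidate genes are fixed in present-day polar bears, whether each fixed
    allele arose from standing variation or de novo mutation (polarized
    against two outgroup genomes), and whether fixation pre- or post-dates
    two Late Pleistocene polar bear genomes. Includes an ancient-DNA
    damage-aware validation of heterozygous calls in the ancient individuals
    (minor-base-proportion and read-position rules), a per-gene dosage PCA
    check of polar/brown differentiation, and a fully self-contained
    synthetic-cohort generator (reference, gene models, genotypes, damaged
    reads and a planted truth table) that makes every stage verifiable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
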