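Package: kinwin
Title: Relatedness Inference from Windowed Identity-by-State in Whole-Genome Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers 1st- to 5th-degree genetic relationships (plus twin/self,
    related-at-unknown-distance, and unrelated) between pairs of individuals
    from whole-genome biallelic SNV calls. The genome is segmented into
    fixed-size non-overlapping windows; within each window the fractions of
    sites in the three identity-by-state classes (P0, P1, P2) are computed,
    windows with P0 below a sequencing-error-dependent cutoff are flagged as
    identity windows, and a small classification tree over window-level
    summary statistics emits a relationship call. Includes a gene-dropping
    pedigree simulator (synthetic founders, Poisson recombination, per-genotype
    error injection) used to calibrate the tree thresholds and to validate the
    classifier, readers/writers for VCF, PED+MAP and TPED genotype files, and
    plotting helpers for window-level IBS tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
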