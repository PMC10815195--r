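Package: phagemech
Title: Mechanical Feature Profiling and Comparison of Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based profiling of the mechanical properties of
    bacteriophage (and other small) genomes. Computes dinucleotide
    frequencies and 16x16 differential-frequency matrices, pairwise
    distance distribution functions (PDDF) with a spectral periodicity
    scan, sliding-window intrinsic-cyclizability profiles under a
    pluggable linear dinucleotide model (50-bp windows, 7-bp stride),
    and pentamer-lookup DNA shape tracks (minor groove width, propeller
    twist, roll, helical twist) with their pairwise correlations.
    Includes a seeded synthetic-genome simulator (i.i.d. and first-order
    Markov, with optional planted periodic dinucleotides), comparative
    statistics (one-way ANOVA with F-critical, Mann-Whitney U, Tukey
    boxplot summaries), and an end-to-end two-genome comparison report
    with table export and heatmap rendering.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
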