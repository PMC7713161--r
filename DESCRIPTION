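Package: atshift
Title: Base-Composition Parity and [AT]-Increase Analysis for Allopolyploid Subgenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying nucleotide-composition change in allopolyploid
    populations such as hexaploid bread wheat. Implements base-composition and
    second-parity-rule (PR2) statistics on reference sequences, dosage-weighted
    [AT] values across polymorphic sites with sliding-window and region
    stratification, Duncan's multiple range test for group comparisons, a
    seven-class SNP functional annotator, transition-type and tri-nucleotide
    mutation spectra with high-frequency motif detection, private-variant
    calling against progenitor panels with donor/derived mutation-rate
    estimation, and a kinship-based linear mixed model scan that treats a
    subgenome's [AT] value as a quantitative genome phenotype. A seeded
    synthetic-data generator emulates allopolyploid domestication (three
    subgenomes, wild and domesticated groups, GC-to-AT biased mutation spectra
    with motif hotspots, bottleneck and selective sweeps) so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
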