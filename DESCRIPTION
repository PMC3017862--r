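Package: corrmut
Title: Correlated Mutation Analysis for Families of Interacting Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects coevolving residue pairs within and between members of a
    family of interacting proteins from multiple sequence alignments, using a
    BLOSUM-based site variability statistic with optional Poisson divergence-time
    normalisation and a correlation cutoff. Includes ortholog-set assembly
    (best-hit assignment, within-species identity clustering, representative
    selection), validation of correlated pairs against structure distances,
    interaction motifs and SNPs with resampling-based significance, conservation
    of correlated mutations across family members with column-entropy
    comparisons, coiled-coil helix periodicity statistics with a random-stretch
    null, and a synthetic-data generator that plants compensatory column pairs
    so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
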