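Package: szprior
Title: Multi-Domain Candidate-Gene Prioritization and Enrichment Testing for
    Schizophrenia Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate genes under linkage peaks by combining three
    evidence domains (differential-expression p-values, proximity to seed
    genes in a protein-protein interaction network, and literature-category
    hits) into a single rank-based score; selects genes for genotyping by
    neurodevelopmental hypothesis and by rank under a SNP budget; summarizes
    per-SNP family-based association results by selection category; tests
    category enrichment against SNP-count-matched random gene sets drawn from
    genome-wide association study (GWAS) universes with plus-one empirical
    p-values; and meta-analyzes candidate SNPs across studies with an
    inverse-variance fixed-effects model and Cochran's Q / I-squared
    heterogeneity screening. Ships a synthetic-data generator emulating every
    input with controllable planted signal, so the whole pipeline is
    exercisable without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
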