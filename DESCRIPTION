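Package: kmeflow
Title: Quantitative Lysine Methylome Analysis from Isobaric-Label Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tidy pipeline for quantitative analysis of protein lysine
    methylation (Kme) from tandem-mass-tag (TMT) proteomics experiments.
    Reads search-engine export tables (protein and modified-peptide
    quantification), filters by FDR confidence and site-localization score,
    normalizes methylated-peptide abundances to parent-protein abundances to
    isolate methylation-stoichiometry changes, and calls differential
    methylation across conditions with one-way ANOVA, Tukey pairwise
    comparisons and Benjamini-Hochberg correction. Builds signed weighted
    co-expression networks with topological-overlap clustering into modules
    and hypergeometric over-representation analysis. Includes methylation-aware
    in silico protease digestion (trypsin/lys-C and chymotrypsin) with
    peptide mass, charge and detectability prediction, residue-level site
    mapping and annotation against known-site and clinical-variant tables,
    and a ground-truth synthetic-data generator emulating a two-protease,
    three-stage, four-replicate TMT study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
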