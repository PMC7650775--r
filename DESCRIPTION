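Package: baculokit
Title: Characterization of Baculovirus Genomes: ORFs, Promoters, Repeats,
    Homology and Species Demarcation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for desk-scale characterization of small circular
    dsDNA viral genomes, modelled on the granulovirus (Betabaculovirus)
    annotation workflow: circular-genome ORF prediction with a minimal-overlap
    filter, screening of upstream regions for the three baculovirus promoter
    element classes, discovery of homologous repeat regions (hrs) with
    palindromic cores and of AT-rich direct repeats (drs), gene-content
    classification against a curated core/conserved gene panel, gene parity
    plots with a collinearity statistic, Kimura two-parameter distances with
    pairwise deletion feeding the 0.05 substitutions/site species-demarcation
    rule, and neighbor-joining trees. Includes a seeded synthetic-genome
    generator with full ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
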