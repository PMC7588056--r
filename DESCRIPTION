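Package: plastidscan
Title: Plastid Marker-Region Discovery by Tajima's D Window Scanning and
    Modal-Ks Divergence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering short plastid (chloroplast) genomic
    regions whose variation recapitulates whole-plastome species phylogeny.
    Implements sliding-window nucleotide diversity (pi), Watterson's theta
    and Tajima's D with gap-aware site handling; neutrality-threshold
    selection of well-aligned alignment blocks and construction of
    segregating-site genotype matrices; Nei-Gojobori (1986) synonymous
    substitution rates (Ks) with modal-value extraction and all-vs-all
    divergence matrices; Tamura-Nei (1993) distances, neighbor-joining and
    UPGMA trees with site-resampling bootstrap and Robinson-Foulds
    comparison; GenBank-level coding-gene curation and plastome
    quadripartite (LSC/IR/SSC) structure detection; and a seeded synthetic
    plastome simulator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
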