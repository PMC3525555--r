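Package: coaldelim
Title: Coalescent-Based Species Delimitation on Ultrametric Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular species delimitation from multi-locus
    sequence data: general mixed Yule-coalescent (GMYC) model fitting on
    ultrametric chronograms with single- and multiple-threshold searches,
    lineage-through-time curves, genealogical concordance scoring of
    putative species across single-locus gene trees, multispecies-coalescent
    likelihood comparison of delimitation scenarios via maximum-tree species
    trees, and Fitch-parsimony homoplasy indices with contingency tests for
    phenotype-clade association. Includes seeded simulators (Yule species
    trees, multispecies-coalescent gene trees, mixed species/population
    trees, clade-associated discrete characters, Jukes-Cantor alignments)
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
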