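Package: karyotree
Title: Phylogenetic Inference from Chromosome Rearrangement Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring phylogenies from comparative chromosome
    painting data. Homology maps relating a putative ancestral avian
    karyotype (PAK/GGA nomenclature) to descendant karyotypes are parsed
    from tab-separated tables, screened for fusion and fission events, and
    coded into binary presence/absence character matrices. A maximum
    parsimony engine (Fitch counting, exhaustive enumeration of unrooted
    topologies, random-addition TBR heuristic search, nonparametric
    bootstrap, strict and majority-rule consensus, consistency/homoplasy/
    retention indices, Robinson-Foulds distances) analyses such matrices,
    and a seedable karyotype-evolution simulator (fusion, fission,
    inversion along a known tree) provides ground truth for end-to-end
    validation. Ships transcriptions of published parrot (Psittaciformes)
    homology tables as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
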