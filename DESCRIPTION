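Package: surrogacy
Title: Effectiveness and Consistency of Indicator Groups in Reserve Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating surrogate (indicator) species groups in
    systematic conservation planning. Builds candidate indicator groups from a
    species-by-site presence/absence matrix (taxonomic orders, species-poor
    orders, threatened, endemic and restricted-range species), solves
    minimum-set-coverage and budget-constrained maximal-representation
    reserve-selection problems with a simulated-annealing solver (plus greedy
    and exhaustive baselines), and classifies groups as effective and
    consistent against null (random species set) and ideal (all species)
    models using two-way ANOVA with Tukey HSD contrasts. Includes a synthetic
    assemblage generator producing paired regions with contiguous
    spreading-dye ranges, right-skewed occupancy, clumped endemics and
    range-size-biased threat status, so the whole pipeline runs without
    external range-map data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
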