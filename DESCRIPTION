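Package: fishbeta
Title: Temporal and Spatial Beta-Diversity Analysis of Species Checklists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing temporal change in freshwater fish (or any
    presence/absence) assemblages across the units of a river-lake basin.
    Builds per-period binary incidence matrices from long-format species
    checklists, computes alpha/gamma richness and extirpation/introduction
    summaries, partitions pairwise Sorensen dissimilarity into spatial
    turnover (Simpson) and nestedness components, ordinates dissimilarity
    matrices by principal coordinates analysis, relates them to geographical
    driver matrices with permutation Mantel tests, and estimates Chao
    richness, sampling completeness and rarefaction curves. Includes a
    seeded synthetic metacommunity generator with controllable
    nestedness/turnover structure, trait-dependent extirpation and exotic
    introductions for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
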