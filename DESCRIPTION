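Package: lepibrain
Title: Phylogenetically Corrected Volumetric Analysis of Insect Brain Neuropils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative volumetrics for insect brain neuropils on a phylogeny.
    Aggregates individual-level neuropil volumes to species means, normalises
    them to a reference brain volume, estimates phylogenetic signal with
    Blomberg's K (permutation and Brownian-motion simulation tests), fits
    phylogenetic generalised least squares (PGLS) allometries with slope and
    grade-shift indices and chi-squared linear-hypothesis tests, clusters
    neuropils by their pairwise scaling slopes, and ships a synthetic-data
    generator that reproduces the statistical structure such studies assume,
    so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
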