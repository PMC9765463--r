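Package: seedasm
Title: Neutral Assembly Models and Phylogenetic Nulls for Single-Seed Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-assembly analysis for bacterial microbiota of individual
    seeds. Fits an immigration/replacement (Moran-type) neutral model to
    species-proportion distributions by generalized moment estimation, with an
    exact small-state-space stationary-distribution oracle for the underlying
    beta-binomial marginals. Implements abundance-weighted beta-mean-nearest-
    taxon distance (betaMNTD), its tip-shuffling null standardization (betaNTI),
    an abundance-based Raup-Crick (Bray-Curtis) null model, the quantitative
    process estimates (QPE) classification of assembly processes, Faith
    phylogenetic diversity, rank-abundance/dominance and seed-to-seedling
    transmission summaries, and a seeded synthetic-study generator that
    emulates the sampling design of single-seed surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
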