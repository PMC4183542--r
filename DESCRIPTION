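Package: cladeshift
Title: Birth-Death Diversification-Rate Shifts on Dated Higher-Taxon Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits constant-rate birth-death diversification models to dated,
    ultrametric phylogenies whose tips are higher taxa (e.g. families) carrying
    extant species-richness counts, using the combined phylogenetic plus
    taxonomic likelihood for terminally unresolved clades. Provides stepwise
    (MEDUSA-style) AIC detection of diversification-rate shifts, likelihood-ratio
    comparison of alternative single-shift placements, observed-versus-expected
    clade-richness ratios with stochastic confidence intervals, robustness of
    shifts across ensembles of dated trees, lineage-through-time curves, and a
    seeded birth-death simulator for generating multi-regime chronograms,
    higher-taxon collapses and pseudo-posterior age ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
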