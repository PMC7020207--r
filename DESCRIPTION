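Package: weedshift
Title: Diachronic Weed-Survey Analysis for Arable Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term change in arable weed communities
    from repeated regional surveys scored on a six-class cover-abundance
    scale. Computes the three facets of species commonness (regional
    frequency, class-midpoint local mean abundance, fidelity to a focal
    crop), classifies species status between two survey periods with a
    stratified bootstrap that equalises sampling effort across regions,
    and relates commonness to species traits through phylogenetic
    generalized least-squares with Pagel lambda and delta branch-length
    transformations and through a Hill-Smith ordination of mixed
    quantitative and qualitative trait tables. A synthetic-survey
    generator with tunable occupancy, abundance coupling and phylogenetic
    trait signal supports testing and power analysis when the original
    monitoring data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
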