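Package: pollselect
Title: Partitioning Phenotypic Selection on Floral Traits Among Co-Occurring Pollinators
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating pollinator-specific phenotypic selection on
    floral traits when several pollinator species forage on the same plants.
    Seed set of each plant is partitioned among visiting bee species from
    flower-visit counts, optionally weighted by species-specific tripping
    rates, giving a relative-fitness measure within each species. Directional,
    quadratic and correlational selection differentials and gradients
    (Lande-Arnold regressions on variance-standardized traits) are estimated
    with case-resampling bootstrap confidence intervals and log-fitness-model
    p-values, and distributional selection differentials (a one-dimensional
    transport distance between the trait distribution and its fitness-weighted
    counterpart) are computed with permutation inference. A calibrated
    synthetic-data generator simulates plant populations, trait-dependent bee
    visitation and tripping-mediated seed set with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
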