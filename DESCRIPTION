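Package: ecoevorange
Title: Individual-Based Eco-Evolutionary Simulation of Plant Range
    Dynamics Under Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, individual-based, spatially explicit
    simulation of perennial plants adapting (or failing to adapt) to
    shifting climate on gridded landscapes. Individuals carry a diploid
    multilocus pleiotropic genetic architecture (continuum-of-alleles
    mutation) controlling three quantitative traits matched to local
    environmental optima. The yearly life cycle couples stage-structured
    demography (seeds with a seedbank, seedlings, pre-reproductive
    adults, adults), Beverton-Holt density-dependent seedling
    competition, and multivariate Gaussian viability selection on
    seedlings. Static-niche-model post-processing (True Skill Statistic,
    TSS-weighted ensemble averaging, presence thresholding, niche-width
    extraction) initialises the simulator, and a synthetic landscape and
    climate-scenario generator makes every component testable without
    external data. Recorders track occupancy change, site suitability,
    adaptive seedling survival, population size, Haldane rates and age
    structure through burn-in and climate-forcing phases.
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
    jsonlite,
    optparse
Config/testthat/edition: 3
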