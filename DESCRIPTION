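Package: riverlake
Title: Community Assembly Analysis Along River-Lake Continua
Version: 1.0.0
Authors@R: person("Aquatic", "Microbiology Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing microbial community assembly along
    river-lake continua from amplicon sequence variant (ASV) count tables:
    alpha- and beta-diversity with group tests, species-abundance
    distribution (SAD) model fitting and selection (broken-stick, geometric
    series, Volkov neutral, Poisson lognormal), null-model stochasticity
    ratios, spatial eigenfunction (PCNM) and environmental variation
    partitioning, distance-decay and Mantel tests, and signed co-occurrence
    networks with random-matrix-theory thresholding, modularity, node roles
    and small-world statistics. Includes seeded generators for synthetic
    communities under neutral, niche and mixed assembly regimes so every
    stage of the pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
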