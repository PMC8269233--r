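Package: seedtrans
Title: Transmission of Seed and Soil Microbiota to Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Set-based source tracking of seedling microbiota assembled from
    seed and soil community pools. Implements detection rules and prevalence
    matrices on non-rarefied amplicon (ASV) count tables, origin assignment of
    seedling taxa (seed, soil, both, unknown), transmission-success estimation
    per source pool and per abundance class (rare, intermediate, abundant),
    together with the supporting diversity statistics (rarefaction, Chao1,
    Faith's phylogenetic diversity, log10+1 Bray-Curtis, PCoA, multivariate
    dispersion, sequential PERMANOVA) and a community-coalescence simulator
    that emulates a seed-by-soil sowing design with dilution-to-extinction
    manipulation of the soil pool and carries ground truth for parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
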