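Package: nitroPM
Title: Ammonia-Oxidizer Community, Abundance and Nitrification Kinetics in
    Fine Particulate Matter
Version: 0.1.0
Authors@R:
    person("PM", "Microbiology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative workflow for ammonia-oxidizing microorganisms
    (ammonia-oxidizing archaea and bacteria, and complete ammonia oxidizers)
    in fine particulate matter (PM2.5) bioaerosols. Provides marker-gene OTU
    clustering and alpha diversity, neighbor-joining phylogenetics with the
    Jukes-Cantor correction and bootstrap support, qPCR standard-curve
    fitting and absolute abundance per cubic metre of air, blank-corrected
    nitrification-potential rate estimation from incubation time series, a
    model partitioning ammonia oxidation among guilds under cell-specific
    activity scenarios, and Spearman rank correlations with exact permutation
    p-values for small sample sets. Includes seeded synthetic-data generators
    with known ground truth for every input, so the full pipeline is testable
    without field samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
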