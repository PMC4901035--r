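Package: rusitecr
Title: Rumen Fermentation Stoichiometry, Tracer Kinetics and Microbiome
    Statistics for Rusitec and Batch-Culture Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vitro rumen fermentation experiments
    (Rusitec semi-continuous fermenters and batch cultures): volatile fatty
    acid stoichiometry and metabolic-hydrogen balance, 15N isotope-dilution
    partitioning of nitrogen flows and microbial protein synthesis
    efficiencies, gas-production curve fitting with the single-pool
    exponential (France) model, 14C bacterial-release regression for
    protozoal activity, and OTU-table community statistics (rarefying
    normalization, diversity indices, Bray-Curtis distances, UPGMA
    dendrograms, PERMANOVA with reduced-model residual permutation,
    canonical correspondence analysis, Benjamini-Hochberg FDR). Includes a
    synthetic-data generator that emulates the 2x2 factorial study design so
    every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    vegan,
    ape,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
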