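Package: phenokit
Title: High-Throughput Plant Phenotyping and Mixed-Model GWAS Toolkit
Version: 0.1.0
Authors@R: person("phenokit", "developers", role = c("aut", "cre"),
    email = "phenokit@example.org")
Description: Image-derived trait extraction for side-view plant images
    (segmentation, projected area, morphological and grey-level
    co-occurrence texture descriptors), grain counting and grain-shape
    measurement for yield traits, feature-grouped all-subsets regression
    with AIC, adjusted R-squared and PRESS for biomass and leaf-area
    prediction, and a linear mixed-model association scan with
    identity-proportion kinship, likelihood-ratio tests,
    effective-marker significance thresholds and LD clumping. Includes
    seeded synthetic-data generators (plant renders, grain scatters,
    structured genotype and phenotype simulations) so the whole chain is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
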