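Package: nanocluster
Title: Nanoscale Cluster and Calcium Release Unit Analysis for Rendered
    Single-Molecule Localization Microscopy Images
Version: 0.1.0
Authors@R:
    person("nanocluster", "developers", email = "nanocluster@example.org",
           role = c("aut", "cre"))
Description: Quantifies the nanoscale organization of ryanodine receptor
    (RyR2) channel clusters in rendered dSTORM images. Segments clusters
    with an intensity-fraction binary mask, measures cluster areas,
    channel counts and Euclidean edge-to-edge nearest-neighbour
    distances, groups clusters into calcium release units (CRUs) by
    single-linkage at a distance threshold, and compares experimental
    groups with a linear mixed effects model honouring the nesting of
    cells within animals. Ships a synthetic SMLM scene generator
    (clustered channels, blinking localizations, Gaussian rendering) so
    the full pipeline can be exercised and validated without external
    data, plus plain TIFF/CSV/YAML input-output and a command-line
    driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    nlme,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
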