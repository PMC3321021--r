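Package: radiascan
Title: Dominant-Marker Population Genomics for Island Radiations
Version: 0.1.0
Authors@R: person("radiascan", "maintainers", email = "radiascan@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for AFLP-style dominant marker data:
    peak scoring and marker quality control with replicate-based genotyping
    error estimation, Nei-Li distances with neighbor-joining and locus
    bootstrap, threshold MOTU clustering of aligned sequences, hierarchical
    AMOVA with permutation tests, Mantel tests for isolation by distance,
    Bernoulli-mixture model-based clustering with Evanno's delta-K, a Bayesian
    F-model genome scan for outlier loci on population pairs with
    consistent-outlier aggregation, Population Graphs, and landmark-based
    geometric morphometrics. A synthetic-data module generates marker
    matrices, peak profiles, sequences, coordinates and landmarks with the
    statistical structure every downstream stage assumes, so the whole
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
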