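Package: CranioNet
Title: Craniometric Population Affinity via Q-Mode Correlation Distances,
    NeighborNet Split Networks, and Principal Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for distance-based biodistance analysis of cranial
    measurements. Provides a data model for Martin-system craniometric
    measurements of individual specimens and population summary samples,
    standardization of population mean profiles against a grand mean and a
    reference standard deviation donor, Q-mode correlation coefficients and
    the derived 1 - r distance matrix, a complete NeighborNet implementation
    (circular ordering by agglomeration plus non-negative least-squares split
    weights) with SplitsTree-compatible NEXUS output, principal component
    analysis of standardized population means with projection of held-out
    samples, and a synthetic two-cluster population generator for end-to-end
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
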