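Package: ecotyper
Title: Seasonal Microbial Ecotype Delineation by Multi-Method Dimensionality Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares three dimensionality-reduction routes to community
    segmentation of dense 16S amplicon time series: principal coordinate
    analysis with k-means, a from-scratch self-organizing map on a toroidal
    hexagonal grid, and a signed weighted co-abundance network with
    topological-overlap module detection by hybrid k-means. Downstream
    statistics (PERMANOVA, Kruskal-Wallis with post hoc rank-sum tests,
    permutation-based environmental vector fitting on NMDS ordinations) and a
    rule-based ecotype qualification step integrate the three segmentations
    with inferred genetic traits and COG functional profiles. A seeded
    synthetic-community generator emulating seasonal Arctic surface-ocean
    succession provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    mclust,
    jsonlite,
    biomformat,
    optparse
Config/testthat/edition: 3
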