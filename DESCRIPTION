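Package: casanova
Title: Cluster Analysis by Subgroups Using ANOVA for Quantitative
    High-Throughput Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quality control for quantitative high-throughput
    screening (qHTS) concentration-response data. Repeated
    concentration-response profiles within each compound are clustered by
    a compound-specific two-way analysis of variance on binned
    concentrations crossed with repeats, followed by ranked-neighbor
    splitting and per-bin subgroup refinement. Compounds are classified
    into five activity classes relative to an assay noise band, and
    per-cluster AC50 potency is estimated from Hill model fits with
    outlier removal and several aggregation strategies including
    inverse-variance weighting. A simulation framework generates
    synthetic studies from Hill and gain-loss (bell-shaped) curves with
    heteroscedastic noise and scores clustering error rates and potency
    estimator bias and variance against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
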