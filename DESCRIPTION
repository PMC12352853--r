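Package: allomflow
Title: Flow-Similarity Allometry of Tree Branch Networks
Version: 0.1.0
Authors@R:
    person("allomflow", "maintainers", email = "maintainers@allomflow.org",
           role = c("aut", "cre"))
Description: Tools to evaluate flow-similarity and elastic-similarity models of
    tree branch allometry from internode measurement tables. Implements
    standardized major axis (SMA) regression on log-log axes with analytic
    confidence intervals, the closed-form exponent predictions that follow from
    the length-diameter exponent alpha, RMSE-based model competition, quadratic
    curvature classification of bivariate log-log relationships, the
    daughter-to-parent cross-sectional area-ratio test of area-preserving
    (DaVinci) branching, and bin-free maximum-likelihood competition of
    exponential versus power-law size distributions via AICc. Includes a
    seeded branching-network simulator (area-preserving cascade with
    radius-dependent ratio noise, exponential internode lengths, and
    length-diameter allometric coupling) so the full pipeline is testable
    without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
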