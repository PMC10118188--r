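Package: streambaci
Title: Multi-Method Before-After-Control-Impact Inference for Paired
    Watershed Harvest Studies
Version: 0.1.0
Authors@R:
    person("Streambaci", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for detecting pre/post-harvest changes in
    stream responses across treatment groups and individual watersheds in
    paired (BACI) watershed experiments. Implements three complementary
    routes to significance on the same long-format observation table: a
    two-sample Kolmogorov-Smirnov test with exact (enumeration) and
    asymptotic p-values, bias-corrected accelerated (BCa) bootstrap
    confidence intervals for group means with an interval-overlap change
    classification, and dummy-coded factorial partial least squares (PLS)
    regression with leave-one-out RMSECV model selection, Box-Cox response
    transformation search, Kramer-Sugiyama degrees of freedom, Wu jackknife
    coefficient t-tests, wild-bootstrap HC3 confidence intervals, and
    compact letter displays built from CI overlap. A seeded synthetic-data
    generator emulates a 12-headwater + 4-downstream paired watershed
    design with configurable treatment-by-period effects so the whole
    pipeline can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
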