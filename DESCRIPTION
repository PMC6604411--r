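Package: cmspa
Title: Cloud Model-Set Pair Analysis for Clinical Efficacy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-criteria efficacy assessment for chronic-wound (diabetic
    ulcer) treatment combining the normal cloud model with set pair analysis
    (CM-SPA). Expert linguistic judgments of index importance are turned into
    cloud weights (Ex, En, He) by a backward cloud generator; patient index
    values are graded against a five-level severity scheme into one-hot
    evaluation matrices; independent-cloud aggregation yields per-grade cloud
    connection degrees that are interpreted through the 3En rule and the
    maximal connection degree principle. An analytic hierarchy process (AHP)
    arm with principal-eigenvector weighting and Saaty consistency checking
    provides the classical constant-weight comparison. Ships the complete
    worked case study as plain-text fixtures plus a synthetic expert-panel
    generator, forward cloud droplet generation, and delimited-text I/O for
    every table involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
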