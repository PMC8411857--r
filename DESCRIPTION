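Package: vfarch
Title: Archetypal Analysis of Humphrey 24-2 Visual Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits archetypal-analysis models to cohorts of Humphrey 24-2
    total-deviation maps, selects the model order by the residual sum of
    squares elbow and 10-fold cross-validation, decomposes any visual field
    into simplex-constrained archetype weights, calibrates a meaningful-weight
    threshold against a normal control cohort, and computes the signed
    archetype-sum composite score.  Includes a synthetic-data generator for
    papilledema-like cohorts with known ground truth, cohort curation rules
    (reliability filtering, replicate averaging, treatment-failure detection),
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
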