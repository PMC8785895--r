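Package: dmnAging
Title: Age-Related Change in Static and Dynamic Default-Mode Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes within-network functional connectivity (FC) strength and
    sliding-window dynamic FC temporal variability from region-of-interest
    fMRI time series of the default-mode network, and tests diagnosis-by-age
    interaction effects on both measures with ordinary least squares models
    controlling for sex, education, acquisition site and head motion. Includes
    Fisher r-to-z comparison of independent correlations, partial correlations
    with clinical scores, summary-statistic group tests, automatable cohort
    quality control, a validation grid over sliding-window parameters, and a
    reproducible multi-site synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'dmnAging-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'io.R'
    'static.R'
    'dynamic.R'
    'stats.R'
    'simulate.R'
    'qc.R'
    'pipeline.R'
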