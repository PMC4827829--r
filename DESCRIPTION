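Package: dmces
Title: Outlier Detection in the Downs-Mardia Circular Regression Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the Downs-Mardia circular-circular regression model by
    maximum likelihood with grid-search initialization, summarises fit
    quality through the mean circular error (MCEs) of the circular
    residuals, and detects influential observations with the row-deletion
    statistic DMCEs.  Includes Monte-Carlo machinery to calibrate
    upper-percentile cut-off points of DMCEs under clean-data simulation
    and to evaluate the power of the detection procedure under planted
    anti-modal contamination, together with von Mises sampling, circular
    descriptive statistics, CSV input/output in degrees or radians, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
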