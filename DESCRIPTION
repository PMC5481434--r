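Package: glycoMSS
Title: Glycan Marker Quantification and Marker State Space Panel Search for
    Multiplexed Immunofluorescence Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("TMA", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies two glycan antigens (CA19-9 and sTRA) in multi-round
    immunofluorescence images of tissue-microarray cores. Detects signal
    pixels with a parameter-free adaptive detector, derives five marker
    types (total, exclusive and dual-labeled expression) by boolean pixel
    algebra over signal maps, aggregates per core with a presence call,
    relates markers to time-to-progression with nonparametric tests and
    Kaplan-Meier analysis, and selects marker panels with a Marker State
    Space (MSS) threshold scan gated on training sensitivity/specificity,
    with 10-fold cross-validation and a random-label null. A synthetic-data
    module generates core images and patient cohorts with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
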