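Package: erpmicro
Title: Microstate, Topographic Randomization and Source Statistics for ERP Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-subject event-related potential (ERP)
    studies with two-by-two within-subject designs. Implements reference-free
    topographic statistics (global field power, global map dissimilarity,
    topographic consistency test, topographic analysis of variance with
    duration-based multiple-testing control), microstate segmentation by
    modified k-means with split-half cross-validated selection of the number
    of maps, randomization tests on microstate parameters (onset, offset,
    duration, area under the curve), a standardized distributed-source
    inverse on toy lead fields with max-statistic permutation tests, and
    Jeffreys-Zellner-Siow Bayesian paired t-tests on region-of-interest
    source activity. Includes a synthetic-data generator that plants a known
    sequence of quasi-stable topographies, condition-specific latency shifts
    and toy source configurations so that every statistic can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
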