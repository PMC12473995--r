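Package: fcewater
Title: Entropy-Weighted Fuzzy Comprehensive Evaluation of Surface Water Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for grading surface-water quality with the entropy
    weight - fuzzy comprehensive evaluation (FCE) method: min-max
    standardization, information-entropy indicator weights, triangular and
    semi-trapezoidal membership functions over the five Chinese
    surface-water classes (GB 3838-2002 grades I-V), maximum-membership
    grade assignment with an ambiguity margin, single-factor compliance and
    exceedance statistics, an entropy-weighted water quality index (EWQI)
    comparator, and source-resolved pollutant-emission accounting. Includes
    a synthetic monitoring-site generator with moment-matched, winsorized
    marginals and an upstream-to-downstream degradation gradient for
    reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
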