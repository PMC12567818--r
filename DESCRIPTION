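Package: fuzzydust
Title: Fuzzy Health-Risk Assessment of Toxic Metals in Road Dust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty-aware human health-risk assessment for toxic metals
    in urban road dust. Concentrations and sensitive exposure parameters are
    represented as triangular fuzzy numbers and propagated through
    bioaccessibility-adjusted USEPA/HJ 25.3-style exposure equations by
    alpha-cut interval arithmetic, yielding fuzzy hazard-quotient, hazard-index
    and carcinogenic-risk intervals that are classified into risk levels I-V by
    membership degree. Includes seasonal descriptive statistics with
    screening-value exceedance, SBET bioaccessibility summaries, and a
    calibrated synthetic sample generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
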