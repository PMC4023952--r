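Package: lazystat
Title: Lazy Exemplar-Sampling Models of Intuitive Statistical Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intuitive statistical judgment as lazy sampling from
    an exemplar memory. Generates constrained stimulus sequences (uniform
    overall, with unimodal and bimodal Beta-shaped halves), scores judgments
    of distribution shape with a signed decile-bin Shape Index and deviation
    measures for central tendency and variability, simulates synthetic
    participants under uniform, recency- or primacy-weighted retrieval (and
    an eager on-line comparator), and analyses the resulting response tables
    with mixed between-within ANOVA, serial-order error analysis, and
    noncentral-F power computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
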