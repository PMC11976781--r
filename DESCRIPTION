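Package: bodbench
Title: Benefit-of-the-Doubt Composite Indicators for Hospital KPI Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite performance indicators for panels of hospital
    key performance indicators using optimistic and pessimistic
    Benefit-of-the-Doubt (BoD) linear programs, with multiplier-share and
    pie-share weight restrictions. Includes direction-aware min-max
    standardization to the (0.01, 1] scale, multiple imputation of missing
    KPI cells by truncated-interval draws, meta-frontier scoring within peer
    groups, benchmark-frequency and pre/post-shock analytics, and a
    seed-deterministic synthetic hospital-KPI panel generator with ground
    truth for method validation. Linear programs are solved by a built-in
    dense two-phase simplex (compiled) applied to the dual, with an
    independent vertex-enumeration oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
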