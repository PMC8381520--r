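Package: kneebench
Title: Noninferiority Benchmarking of Knee Replacement Constructs from
    Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Benchmarks total knee replacement (TKR) constructs against a
    dynamic internal best-practice reference using arthroplasty registry
    data. Per-construct all-cause revision ("net failure") is estimated
    with the 1-Kaplan-Meier product-limit method with Greenwood variance,
    a reference construct is selected as the lowest-failure construct with
    sufficient numbers at risk, and every eligible comparator is
    classified against 20% and 100% relative-risk noninferiority margins
    at fixed post-operative time points via a Wald comparison of failure
    differences. Includes a synthetic registry generator (constant
    revision and death hazards, staggered enrolment, administrative
    censoring at data lock) so the whole pipeline is testable without
    access to confidential registry extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
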