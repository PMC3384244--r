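Package: rppfeedback
Title: Modeling Stress-Feedback-Regulated Recombinant Protein Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Delay-differential-equation model of an IPTG-inducible
    T7/GFP expression circuit carrying a stress-induced TetR negative
    feedback loop, together with inclusion-body partitioning of the
    recombinant product. Provides a method-of-steps simulator with a
    brute-force verification oracle, a synthetic plate-reader data
    generator with clone-to-clone variability, multi-start parameter
    estimation from fluorescence time courses, local sensitivity
    analysis, cross-validation, and variant comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
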