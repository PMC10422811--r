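Package: triarmni
Title: Non-Inferiority Tests for Three-Arm Trials on CV-Adjusted Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-inferiority testing in three-arm (gold-standard) trials where
    treatment effects are measured as Searls coefficient-of-variation-adjusted
    means, allowing heteroscedasticity between the placebo arm and the active
    arms. Implements a generalized-pivotal-quantity test with Monte-Carlo
    generalized p-values and confidence limits, together with a Delta-method
    competitor and a stratified residual-bootstrap competitor, plus a
    scenario-driven simulation engine for type-I-error, power and
    estimator-property studies under normal, log-normal and gamma outcome
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
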