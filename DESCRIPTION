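Package: isobolr
Title: Non-Linear Isobolographic Analysis of Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose-response and isobolographic synergy analysis for fixed-ratio
    drug-combination studies in behavioral pharmacology. Normalizes raw
    behavioral measurements to percent maximum possible effect (%MPE), fits
    three-parameter Hill dose-response curves, builds the Loewe dose-equivalence
    predicted-additive effect surface for two drugs with different maximal
    effects and Hill slopes, computes predicted-additive ED50s with delta-method
    standard errors along a fixed-ratio ray, draws non-linear and linear
    additivity isoboles, and tests experimental against predicted ED50s with an
    unpaired t-test. A synthetic data generator emulating a chronic constriction
    injury (CCI) neuropathic-pain study makes the full pipeline testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
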