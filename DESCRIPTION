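Package: thresholdrisk
Title: Desperation Thresholds and Risk Taking in Survey Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how risk taking responds to poverty under a
    desperation-threshold utility model. Implements the threshold utility
    function and its certainty-equivalent predictions, a seeded generator of
    synthetic longitudinal survey panels (income, unavoidable costs,
    subjective insecurity items, multiple-price-list gamble and delay
    batteries), derivation of objective and subjective resource measures,
    segmented (broken-stick) mixed-effects regression with a
    maximum-likelihood changepoint search, polynomial mixed-model comparison,
    and variance-heterogeneity analyses (group variance-ratio tests,
    squared-residual regressions, threshold sweeps, within-person stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
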