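Package: larimorph
Title: Phylogenetic Comparative Analysis of Gull Wing Morphometrics and Pigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between wing morphology and
    wing pigmentation across gull (Larinae) species. Derives wing area, wing
    loading and aspect ratio from standard field measurements; fits
    phylogenetic generalized least squares regressions of mantle darkness
    under non-phylogenetic, Brownian-motion, Ornstein-Uhlenbeck and Pagel's
    lambda covariance models with likelihood-ratio model selection; fits a
    beta regression with logit link and a phylogenetic random effect for the
    proportion of black on the wingtips via a Laplace-approximate marginal
    likelihood; reconstructs ancestral states of continuous traits under
    Brownian motion; and runs a simulate-and-refit model-adequacy check.
    A seeded synthetic-data generator produces trees and trait tables with
    the statistical structure the analyses assume, so every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
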