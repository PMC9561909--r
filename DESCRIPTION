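Package: stemtaper
Title: Variable-Exponent Stem Taper Equations with Stand-Density Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling stem taper (the decrease of stem diameter
    with height along a tree bole) in plantation forestry. Provides a
    registry of twelve variable-exponent taper equations, a density-augmented
    Kozak (2004) form in which stand density enters the variable exponent,
    and three estimation engines: pooled nonlinear least squares,
    tree-level nonlinear mixed-effects estimation via a Laplace-approximated
    marginal likelihood with exhaustive search over one- and two-coefficient
    random-effect placements, and nonlinear quantile regression by smoothed
    check-loss minimisation over a grid of quantiles. Includes the standard
    taper evaluation statistics (MAB, RMSE, MPB, Bias, R2, adjusted R2,
    AIC, BIC), position-wise error summaries along the stem, a synthetic
    stem-analysis data generator emulating a destructively sampled
    plantation design, and a comparison/validation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
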