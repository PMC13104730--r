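Package: illfit
Title: Incipient Limiting Level Estimation from Zooplankton Life-History Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the incipient limiting level (ILL) -- the food
    concentration above which a fitness trait no longer increases -- from
    per-individual zooplankton life-history records collected along a food
    gradient. Computes per-individual somatic growth rates and early-life
    intrinsic rates of increase (numerical Euler-Lotka solution), fits
    clone-specific quadratic-plateau and piecewise-linear (hockey-stick)
    saturation curves by nonlinear least squares, derives the ILL, plateau
    elevation and threshold food level (TFL), and attaches nonparametric
    stratified bootstrap percentile confidence intervals. Ships a
    synthetic-data generator emulating a 4-clone x 12-concentration x
    10-replicate Daphnia feeding experiment so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
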