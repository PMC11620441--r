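Package: greyroll
Title: Grey Forecasting Models with Metabolic Rolling-Window Updating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grey system forecasting for short, positive, annual count
    series such as accident fatality records. Implements the discrete
    nonhomogeneous grey model DNGM(1,1) built on the whitening equation
    dx1/dt + A*x1 = B*t + C, together with the classical GM(1,1),
    DGM(1,1), and the indirect (IDGM) and direct (DDGM) discrete
    variants, each with a uniform fit/simulate/extrapolate contract.
    A metabolic rolling engine turns any static model into a dynamic
    one-step-ahead forecaster (MGM and DNMGM when applied to GM and
    DNGM) by sliding a fixed-size window over the series, and selects
    the window size by minimising the mean absolute percentage error
    over candidate sizes. Includes a seeded synthetic-series generator
    for exact, noisy and structural-break regimes, a model-comparison
    workflow ranked by MAPE, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
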