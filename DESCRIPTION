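Package: leafprofile
Title: Individual Leaf Size Profiles for Maize, Sorghum and Pearl Millet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts blade length, blade width and leaf area for every
    main-culm leaf position of maize, sorghum and pearl millet from the
    total leaf number (TLN), using a three-phase expolinear-logistic model
    of leaf size by leaf position. Ships species-generic parameter sets and
    the full calibration pipeline: per-TLN-group nonlinear least-squares
    fits, regression of the largest-leaf position and logistic decay rate
    on TLN (linear, segmented and decline-then-plateau forms with free
    breakpoints), robust bivariate outlier screening of decay-rate
    estimates, and goodness-of-fit summaries. Includes a synthetic
    leaf-measurement generator for parameter-recovery testing and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
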