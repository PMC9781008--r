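Package: dnjftir
Title: Chemometric Quantification of 1-Deoxynojirimycin from ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration toolkit for quantifying
    1-deoxynojirimycin (DNJ) in white-mulberry herbal products from
    ATR-FTIR absorbance spectra. Implements weighted-least-squares
    baseline removal, standard normal variate scaling and autoscaling,
    Kennard-Stone calibration/test splitting, NIPALS PLS1 regression with
    leave-one-out cross-validation, stepwise-forward interval PLS variable
    selection, Y-randomization robustness testing and Williams-plot
    applicability-domain diagnostics, together with the companion
    wet-chemistry calculations (ICH Q2 LOD/LOQ, recovery, relative
    standard deviation, DPPH EC50, content conversion and dietary-intake
    coverage) and a seeded synthetic-spectra generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dnjftir-package.R'
    'io.R'
    'ipls.R'
    'pls.R'
    'preprocessing.R'
    'sampling.R'
    'synthetic-data.R'
    'utils.R'
    'validation.R'
    'wetchem.R'
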