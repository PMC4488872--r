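Package: aquaphot
Title: Aquaphotomic Chemometrics for Near-Infrared Spectra of Aqueous Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for near-infrared (NIR) spectra of aqueous
    solutions, built around the aquaphotomics view of the 1300-1600 nm first
    overtone of water. Provides delimited-text spectra input/output, spectral
    pretreatments (moving-average and quadratic polynomial smoothing, mean
    centering, orthogonal signal correction), latent-variable models (PCA,
    NIPALS partial least squares regression, principal component regression,
    PLS discriminant analysis, SIMCA class modeling with interclass distances
    and discriminating power), leave-one-out and group hold-out
    cross-validation with SEC/SECV calibration metrics, a curated water
    absorbance band table (C1-C12, W1-W3) with regression-vector peak
    detection and band annotation, a seeded generator of synthetic NIR-like
    water spectra with solute- and photoproduct-dependent band perturbations,
    and a config-driven pipeline that runs complete classification and
    calibration experiments with JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
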