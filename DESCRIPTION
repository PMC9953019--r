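Package: pulsewss
Title: Pulsatile Hemodynamics Post-Processing and Robust Factorial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-solver analysis toolkit for pulsatile vascular flow
    simulations. Builds Parabolic, Plug, and Womersley inlet velocity
    profiles from a sampled cardiac waveform; evaluates generalized
    Newtonian blood viscosity laws (Carreau-Yasuda, Casson,
    Herschel-Bulkley, Newtonian, power law); computes wall-shear-stress
    indices (TAWSS, OSI, RRT) with thrombus-prone area thresholds;
    quantifies cross-sectional flow asymmetry and dispersion; verifies
    grid convergence via the Grid Convergence Index; and analyses
    factorial simulation campaigns with outlier- and
    heteroscedasticity-robust trimmed-mean two-way ANOVA and Yuen-type
    post hoc contrasts under Hochberg family-wise error control.
    Synthetic generators with analytic ground truth replace the CFD
    solver for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
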