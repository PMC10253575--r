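Package: aortastiff
Title: Aortic Stiffness from Simulated 4D Flow MRI Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for aortic stiffness
    quantification from time-resolved aortic flow-rate curves. Generates
    synthetic aortic centerlines and propagating flow waveforms with known
    ground-truth pulse wave velocity (PWV), estimates inter-plane transit
    times with a cross-wavelet phase method and classical alternates,
    converts transit times, lumen areas and central pressures into the four
    standard stiffness measures (carotid-femoral PWV, two-plane PWV,
    multi-plane PWV, aortic distensibility), and reproduces case-control
    statistics: normality-gated group comparisons, correlation matrices and
    ROC analysis with Youden-optimal thresholds. Includes a Gaussian-copula
    cohort simulator calibrated against published group marginals and
    pooled cross-method correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
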