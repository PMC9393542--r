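Package: grainrisk
Title: Probabilistic Dietary Risk Assessment of Potentially Toxic Elements in Wheat Grain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for human-health risk assessment of co-occurring potentially
    toxic elements (Cr, Ni, As, Cd, Pb, F) measured in wheat grain. Implements
    descriptive statistics with coefficient-of-variation classification and
    standard-limit exceedance screening, Spearman correlation and principal
    component analysis with Kaiser-Meyer-Olkin and Bartlett sphericity
    diagnostics for source identification, deterministic and Monte Carlo
    hazard quotient / hazard index and carcinogenic risk computation for
    children, adult females and adult males, contribution-to-variance
    sensitivity analysis, and a Gaussian-copula synthetic concentration
    generator for testing the pipeline without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
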