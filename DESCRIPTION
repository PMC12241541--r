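Package: wmdynamics
Title: Time-Resolved Analysis of Working-Memory BOLD Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for whole-brain analysis of working-memory
    manipulation in task fMRI. Provides a synthetic generator for
    parcellated BOLD time series with a blocked mental-rotation design,
    finite impulse response (FIR) deconvolution GLMs with day/scan
    nuisance structure, timepoint-resolved PCA + linear discriminant
    axes under subject-grouped cross-validation, Gram-Schmidt
    orthogonalization and quadrant-based region selection, net-BOLD
    difficulty statistics with FDR control, cross-correlation delay
    detection, and kernel-density energy landscapes, plus trial-level
    behavioral mixed models for accuracy and response time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
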