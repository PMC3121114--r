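Package: xlnrdyn
Title: Dynamics and Stability of the XlnR Regulon Transcription-Translation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modeling of the D-xylose-induced XlnR regulon of
    Aspergillus niger as a coupled transcription-translation system of
    ordinary differential equations with Hill regulation, a decaying
    D-xylose input, and an optional delayed feedback channel onto the
    master xlnR gene gated by the carbon-catabolite repressor CreA.
    Provides simulation with and without delayed feedback, analytic
    Jacobians, eigenvalue stability and oscillation analysis, closed-form
    thresholds for master-protein autoregulation, feedback-gain scans with
    bisection-refined bifurcation points, promoter-occupancy summaries,
    and a synthetic-scenario generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
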