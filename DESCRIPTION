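Package: tmshotspot
Title: Closed-Loop TMS Motor Hotspot Hunting with Warped Gaussian
    Processes and Bayesian Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Concurrent optimization of transcranial magnetic stimulation
    (TMS) coil location and rotation angle for motor hotspot hunting. A
    square-root-warped Gaussian process models motor-evoked-potential (MEP)
    amplitude over the coil parameters (x, y, theta); five acquisition
    functions (upper confidence bound, expected improvement, Thompson
    sampling, knowledge gradient, max-value entropy search) and a random
    baseline drive the closed-loop search. Includes a generative MEP
    simulator built from ground-truth warped GPs, center-of-gravity and
    NRMSE map metrics on a circular test grid, and a benchmark harness
    for initialization and acquisition-function studies on synthetic
    subject ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    MASS,
    optparse
Config/testthat/edition: 3
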