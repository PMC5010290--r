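Package: leukowalk
Title: Leukocyte Random-Walk Model Selection via Multi-Objective Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise 3D leukocyte cell-track data and to select
    among candidate random-walk motility models. Implements motility profiling
    (translational and turn speeds, meandering indices, mean squared
    displacement, displacement autocorrelation), a bias-aware framework for
    fitting statistical distributions to track speed data that reproduces the
    observation bias of a finite imaging volume, six 3D random-walk models
    (Brownian motion, Levy walk and four correlated random walks) simulated in
    a continuous-space arena with an imaging-volume observation process, and
    multi-objective (NSGA-II) calibration of each model against a target
    motility profile with Pareto-front based model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
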