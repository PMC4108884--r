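Package: flowgraphsurv
Title: Flowgraph Semi-Markov Modelling of Recurrence and Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-Markov multistate analysis of the recurrence-progression
    process in non-muscle-invasive bladder cancer via flowgraph models.
    Per-transition waiting-time distributions are estimated by Kaplan-Meier
    and approximated by mixtures of Erlang (phase-type) distributions fitted
    with a non-negative least-squares initialization followed by constrained
    minimization of the CDF discrepancy.  Branch Laplace transforms are
    combined by series/parallel flowgraph rules into the normalized
    first-passage transform from disease-free to progression, which is
    inverted numerically (Abate-Whitt EULER algorithm) to yield parametric
    density, survival and hazard curves.  Includes a homogeneous
    continuous-time Markov baseline for comparison and a synthetic
    multistate cohort generator with right censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    survival,
    pracma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
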