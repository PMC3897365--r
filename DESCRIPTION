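Package: angiomet
Title: Organism-Scale Simulation of Metastasis Under Systemic Inhibition
    of Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation and calibration of a structured-
    population model of cancer at the organism scale. Each lesion (the
    primary tumor and every metastasis) carries a volume and a dynamic
    carrying capacity under angiogenic control; lesions seed new
    metastases at a volume-dependent rate and all lesions secrete a
    circulating angiogenesis inhibitor that couples them systemically.
    The package provides the rate laws and biophysical parameter
    derivations, a Lagrangian cohort scheme for the transport equation
    with renewal boundary condition, an independent renewal-equation
    solver used for validation, two-stage least-squares calibration to
    growth-curve and metastatic endpoint data, and a generator of
    synthetic datasets emulating the 4T1 mouse experiments used for
    fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
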