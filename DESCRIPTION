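Package: radiosens
Title: Multi-Endpoint Modelling of Individual Radiosensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the quantitative links between clinical radiotoxicity
    severity (CTCAE grade) and the major cellular radiosensitivity endpoints
    measured in untransformed human fibroblasts after 2 Gy X-rays: clonogenic
    survival (SF2), residual micronuclei, residual gamma-H2AX foci, and
    maximal early pATM foci.  Provides a seeded synthetic cohort generator
    emulating a 200-line fibroblast collection, linear-quadratic survival
    curve fitting, least-squares fitting and selection of candidate
    inter-endpoint laws, derivation of the coupled k0-k4 coefficient system
    with numerical consistency checks, one-way ANOVA discrimination of
    endpoint distributions across grades, and grade prediction by inversion
    of the fitted laws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
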