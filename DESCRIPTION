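Package: shorestab
Title: Stability Decomposition and Piecewise SEM for Intertidal
    Community Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse how substrate heterogeneity shapes the
    multiyear temporal stability of intertidal communities surveyed as
    percent cover on paired experimental tiles along an emersion-stress
    gradient.  Implements per-tile stability decomposition (temporal
    stability as the inverse coefficient of variation after linear
    detrending, population stability, Loreau-de Mazancourt synchrony,
    statistical averaging and compositional stability), nested
    mixed-effects models of treatment-by-gradient effects, multigroup
    piecewise structural equation modelling with d-separation tests and
    Fisher's C, and path-tracing of cascading (indirect) effects with
    cluster-bootstrap uncertainty.  A synthetic multitrophic community
    generator with configurable ground-truth causal pathways supports
    calibration and power analysis of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    car,
    vegan,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
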