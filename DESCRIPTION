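Package: wheelstop
Title: Simulation and Analysis of the Wheel Stopping Sense-of-Control Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing a timed-action "wheel
    stopping" behavioural task used to induce and measure the subjective
    sense of control and its coupling with subjective stress. Provides a
    deterministic trial-physics engine and probe scheduler, synthetic-cohort
    generators with the mixed-model structure assumed by the analyses, a
    trial-by-trial exponentially smoothed regression model of control
    ratings fit by maximum a posteriori estimation with BIC model selection,
    split-half internal consistency via the two-way absolute-agreement
    intraclass correlation ICC(A,1), linear mixed-effects analyses of
    stress-control coupling and stress buffering with estimated-marginal-
    means timepoint contrasts, Benjamini-Hochberg adjustment, and a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
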