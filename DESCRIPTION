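Package: cycleASF
Title: Cell-Cycle Desynchronization Analysis via the Auto-Similarity Function
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how synchronized populations of cycling
    cells lose synchrony over time. Provides a phenomenological single-cell
    interphase DNA-content model with error-in-variables noise on the cycle
    period and initial DNA content, a population simulator emulating
    double-thymidine-block release and asynchronous-control flow-cytometry
    experiments, the auto-similarity function (the two-sample Kuiper
    statistic applied to successive timepoints of an evolving DNA-content
    distribution), logistic decay-rate fitting of desynchronization curves,
    a simplified Dean-Jett-Fox DNA-histogram phase classifier, and a
    simulation-based estimator of cell-cycle period variability from an
    observed desynchronization curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
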