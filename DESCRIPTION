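Package: resistsim
Title: Conjoint Normal-Tumor Models of Chemotherapy with Intrinsic and
    Drug-Induced Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator for coupled ordinary differential
    equation models of normal and tumor cell populations under chemotherapy,
    covering both intrinsic (mutation-at-division) and drug-induced
    resistance. Tumor subclones (wild, mutated, resistant) grow logistically
    against a shared carrying capacity, interact with one or two drugs
    through a saturating pharmacodynamic kill term, and feed back on normal
    tissue through a critical-size coupling term. The package provides the
    model right-hand sides term by term, concentration schedules (constant
    or exponentially decaying) with hard-switch gating of mutation and
    conversion terms, a discontinuity-aware adaptive integrator with dense
    output, trajectory analytics (detectability-threshold crossing,
    extinction, dominance), four preset treatment scenarios, initial
    condition calibration by bisection, configuration-file input, tabular
    output, plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
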