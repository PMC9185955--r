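Package: nhecon
Title: Health-Economic Evaluation of Nurse-Led Care Models in Nursing Homes
Version: 0.1.0
Authors@R:
    person("nhecon", "maintainers", email = "nhecon@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the health-economic impact of nurse-led care
    models in long-term residential care from the nursing-home perspective.
    Implements time-driven activity-based costing of implementation process
    maps, intervention (nurse-role) salary costing, accounting of revenue
    losses during resident hospitalisations under three observed billing
    regimes, an incremental cost-effectiveness analysis against usual care
    with cost-effectiveness-plane dominance classification, and a one-way
    deterministic sensitivity analysis rendered as a tornado diagram. A
    seeded generator produces complete synthetic stepped-wedge nursing-home
    ledgers with the statistical structure the analysis assumes, so the whole
    pipeline is testable without access to confidential facility data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
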