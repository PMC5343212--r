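Package: activecost
Title: Costing and Cost-Effectiveness Analysis of Physical Activity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Payer-perspective micro-costing and cost-effectiveness analysis of
    behavioural physical-activity interventions evaluated in two-arm randomized
    trials. Builds itemized per-arm cost ledgers (loaded personnel wages,
    straight-line hardware depreciation, website and materials costs), converts
    repeated-measure weekly MVPA means into cumulative per-person minute gains
    by piecewise-linear interpolation, and computes per-arm and incremental
    cost-per-minute ratios. Includes one-way deterministic sensitivity analysis,
    a fixed/variable enrollment-scaling cost model, an accelerometer bout scorer
    (count threshold, minimum bout duration, wear-time validity), and a
    synthetic-trial generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
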