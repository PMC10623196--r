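Package: myopiacea
Title: Cost-Effectiveness Analysis of Myopia-Control Interventions in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Markov cohort model for the health-economic evaluation of
    interventions that slow myopia progression in children (low-dose atropine,
    defocus-modifying spectacle and contact lenses, orthokeratology, outdoor
    activity, red light therapy) against single-vision lenses. Provides a
    validated parameter schema for per-strategy annual costs and annual
    spherical-equivalent / axial-length treatment effects, a three-state
    (low / moderate / high myopia) cohort engine with irreversible progression
    and discounted cost accrual, incremental cost-effectiveness ratios with
    strong and extended dominance analysis, WHO GDP-threshold classification,
    one-way deterministic sensitivity analysis, seeded probabilistic
    sensitivity analysis with Gamma cost and Normal effect distributions,
    cost-effectiveness acceptability curves over a willingness-to-pay grid,
    and a synthetic parameter-table generator with plantable dominance
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
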