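Package: heatexcess
Title: Heat-Wave Detection, Excess Heat Factor, and Excess Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects heat waves in daily mean temperature series with a
    two-percentile rule, computes excess-heat indices and the cumulative
    excess heat factor (EHF), fits a spline-based quasi-Poisson baseline
    mortality model with a heat-wave-day counterfactual, quantifies excess
    and relative excess mortality per heat wave with exact Poisson
    confidence limits, estimates short-term mortality displacement
    (harvesting) via extended heat-wave periods, and regresses cumulative
    excess mortality on heat-wave characteristics. Includes a seeded
    synthetic-data generator for temperature, stratified mortality, and
    population inputs, plus direct age-standardization of daily death
    counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
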