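Package: phycobatch
Title: Batch Growth-Curve Analysis for Light-Limited and Heterotrophic
    Microalgal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of batch growth curves from multicultivator
    photobioreactor experiments with green microalgae. Corrects the
    nonlinear turbidity-sensor signal with an exponential calibration
    model, segments corrected optical-density curves into exponential and
    deceleration phases, estimates the specific growth rate, doubling
    time, and maximum volumetric biomass productivity, estimates biomass
    yields on organic carbon substrates (glucose, acetate) by endpoint
    and consumption-regression methods, and compares pigment contents
    (chlorophyll a+b, lutein, carotene, as percent of dry weight) across
    light intensities, growth phases, carbon sources, and weak-light
    treatments. Includes a mechanistic generator of synthetic batch
    cultures (Beer-Lambert light-limited photoautotrophy, Monod
    heterotrophy, sensor distortion, replicate noise) so every stage of
    the pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
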