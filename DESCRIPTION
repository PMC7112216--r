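Package: fuelsir
Title: Epidemic Modelling and Optimal Refueling Control of Hurricane Fuel
    Shortages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats regional fuel shortages during hurricane evacuations as a
    contagion: a susceptible-infected-recovered (SIR) compartment model on the
    percent scale, forward-Euler integration at the reporting cadence of
    crowd-sourced outage data, joint state-parameter estimation of the
    transmission and recovery rates with an unscented Kalman filter followed by
    mean-square-error selection of a best-fit constant pair, and bang-bang
    "vaccination analogue" refueling plans whose switching time is set by the
    effective reproduction number crossing one. Includes a synthetic
    shortage-series generator with known ground truth, a registry of per-city
    fitted rates, intervention-level sweeps with a bilinear breakpoint readout,
    and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
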