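Package: cpditools
Title: Predicting Close-Proximity Detection Interference in Passive
    Acoustic Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of close-proximity detection
    interference (CPDI) for passive acoustic telemetry arrays.
    Enumerates direct and reflected propagation paths between a coded
    transmitter tag and a stationary receiver in a flat waveguide with
    the image-source method, classifies multipath arrivals against the
    receiver's blanking interval and average maximum detection radius
    (AMDR), and maps the region where tag transmissions are predicted
    to be rejected. Also includes a waveform-free ping-train decoding
    simulator with multi-tag collision modelling, estimation of
    detection functions, AMDR and CPDI extent from range-test detection
    logs via penalized-spline Poisson regression, receiver performance
    metrics from daily meta-logs, and a seeded synthetic range-test
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
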