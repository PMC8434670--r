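Package: silogrowth
Title: Feed Intake and Growth Monitoring for Fattening Pigs from Silo
    Level Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts raw silo level-sensor readings into cleaned
    feed-weight series, estimates per-animal accumulated feed intake,
    predicts batch weight distributions with a Gompertz growth curve and
    a polynomial variance model, and raises alerts when sensor-based and
    theoretical intake diverge. Includes a ground-truthed simulator of a
    fattening-pig batch fed from a monitored silo, file readers and
    writers for all inputs and outputs, and a small command-line
    front-end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
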