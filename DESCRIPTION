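Package: jvpdome
Title: Grating Orientation Task Protocol with JVP Domes and a
    Transformed Up-Down Staircase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Engine for the grating orientation task (GOT) used to measure
    tactile spatial acuity with JVP domes.  Implements the discrete dome
    ladder, a two-down-one-up staircase with transition-point (reversal)
    detection and reversal-averaged threshold estimation, the surrounding
    practice/training/testing session protocol with its accuracy gates,
    parametric and replayed simulated observers for two-alternative
    forced-choice responding, Monte-Carlo protocol evaluation with an exact
    enumeration oracle for small staircase configurations, and CSV/JSON
    record-table serialization in the 1 = vertical / 2 = horizontal coding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
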