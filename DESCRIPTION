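Package: acetoclast
Title: Two-Population Acetoclastic Methanogenesis in the Anaerobic Digestion Model No. 1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and calibration toolkit for anaerobic digestion of
    volatile fatty acids and maize silage with a modified Anaerobic Digestion
    Model No. 1 (ADM1) in which the acetoclastic methanogen guild is split
    into two competing populations, Methanosarcina and Methanosaeta, each
    with its own uptake kinetics and pH-inhibition window. Includes
    charge-balance pH chemistry, liquid-gas transfer with overpressure-driven
    biogas outflow, continuous and pulsed feeding schedules with organic
    overloading disturbances, mass-balance audits, chemostat washout
    analysis, parameter fitting and recovery experiments against synthetic
    observations, and community analytics (Hill diversity and evenness,
    16S rRNA operon copy-number correction, mrtA duplicate correction,
    13C pathway ratios, and COD-based VFA unit conversions).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
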