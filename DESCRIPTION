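Package: kcurve
Title: Age-Dependent DLP-to-Effective-Dose Conversion for Pediatric Brain CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts the dose-length product (DLP) reported by CT scanners
    into effective dose (ED) for pediatric brain examinations. Fits a
    three-parameter power law y = a(x + b)^c through the ICRP conversion-factor
    anchors at 0, 1, 5 and 10 years ("curve method") and evaluates it at any
    age, alongside piecewise-linear interpolation ("linear method"),
    nearest-anchor lookup ("simple method") and a phantom-binned
    device-style method. Includes batch conversion of dose-record tables,
    per-age and per-age-group cohort summaries (median, mean, SD, CV) of DLP
    and ED, and a seeded synthetic dose-record generator for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
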