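Package: ednaqpcr
Title: Standardized Environmental DNA qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration and quantification pipeline for species-specific
    environmental DNA (eDNA) qPCR surveys. Fits standard curves from serial
    dilutions, models the limit of detection (95% detection probability) and
    the limit of quantification (35% coefficient-of-variation threshold) from
    replicated dilution series, normalizes raw copy numbers for PCR
    inhibition measured with an internal positive control (2^dCq correction),
    gates reactions by LOD/LOQ, converts copies per reaction to copies per
    liter of sampled water, and compares groups with rank-based statistics.
    Includes a synthetic plate and field-survey generator with Poisson
    single-molecule detection so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
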