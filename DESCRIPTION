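Package: protonqa
Title: Log-File Quality Assurance for Spot-Scanning Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance toolkit for pencil-beam-scanning proton
    therapy. Reads planned spot maps from DICOM RT Ion Plan files, reads
    delivered spot parameters from an openly documented binary delivery-log
    format, projects spot-position-monitor coordinates to the isocenter
    plane, and computes spot-wise deviations between plan and delivery.
    Provides distribution summaries, heteroscedastic factor analyses
    (Levene, Welch ANOVA, Games-Howell), and moving-window tolerance
    flagging of systematic spot-position errors against TG-224-style
    tolerances; trains per-axis gradient-boosted models that predict
    delivered spot positions from plan features; and quantifies the
    dosimetric impact of position deviations with a simplified analytical
    pencil-beam dose model. A synthetic delivery simulator generates
    paper-shaped QA campaigns with configurable systematic and random error
    structure and fault injection, so the whole pipeline runs without
    proprietary vendor logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
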