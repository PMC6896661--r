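Package: visualdata
Title: Per-Subject Visual Reporting of Randomized Controlled Trial Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for responder analysis and per-subject visual reporting of
    two-arm, two-timepoint randomized controlled trials. Classifies every
    subject's change on every outcome as improved, no change, worsened or
    missing under four cut-off rules (delta-zero, clinically established risk
    thresholds, tertile/quartile splits, and the minimal detectable difference
    derived from measurement error), renders the per-subject glyph chart (one
    large circle for the primary outcome surrounded by small circles for the
    secondary outcomes, colored green/yellow/red/gray) as standalone SVG, and
    produces the conventional mean (SD) plus mixed-design ANOVA summary table
    for contrast. Includes a moment-matched synthetic trial generator so the
    package's worked examples are fully reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
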