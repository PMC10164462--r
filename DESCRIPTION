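Package: mnfelim
Title: Iron-Manganese Co-Limitation Physiology in a Multi-PFT Quota Box Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-quota (Droop-type) growth physiology for three phytoplankton
    functional types with explicit manganese requirements: manganese use
    efficiency, the photosynthetic and basal Mn quota, a MnSOD/reactive-oxygen
    balance that couples iron stress to manganese demand, Zn-Mn transporter
    competition, and deficiency diagnostics. A desk-scale simulator time-steps
    independent seasonal box models on an idealized Southern-Ocean forcing
    grid (built-in synthetic generator) and runs a factorial set of trait
    experiments, yielding deficiency footprint areas, net primary production
    and carbon-export sensitivities relative to a control run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
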