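Package: sirtdose
Title: Dosimetry and Dose-Response Modelling for Y-90 Radioembolization
Version: 0.1.0
Authors@R: person("Maintainer", "sirtdose", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Treatment-planning dosimetry for selective internal radiation
    therapy (SIRT) with Y-90 glass microspheres. Implements the MIRD
    non-penetrating absorbed-dose arithmetic behind the single-compartment
    (standard) and multi-compartment (partition) prescription models, a logit
    tumor control probability (TCP) model, the Walrand normal tissue
    complication probability (NTCP) whole-liver tolerance dose model with
    numerical inversion, volume-dependent recovery-coefficient partial-volume
    correction, parameterized standard-vs-partition prescription charts of
    TCP change with equivalence-line extraction, NTCP-limited prescription
    planning, a synthetic patient-cohort generator that emulates the
    statistical structure of lobar microsphere treatments, and a
    command-line pipeline with CSV/JSON cohort I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
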