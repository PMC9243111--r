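Package: pdukinetics
Title: Kinetic Modeling of the Encapsulated 1,2-Propanediol Utilization Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic three-region kinetic model of the bacterial
    1,2-propanediol utilization (Pdu) pathway encapsulated in protein
    microcompartments. Contrasts spherical microcompartments (MCPs) against
    cylindrical microtubes (MTs) through a geometry layer with equal-volume
    and equal-surface-area matching, integrates permeability-limited
    Michaelis-Menten reaction networks coupled to batch-culture growth,
    calibrates shell permeability and aldehyde-consuming enzyme activities
    against timescale and toxicity criteria, performs normalized local
    sensitivity analysis, and generates synthetic growth-curve and HPLC-style
    metabolite datasets for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
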