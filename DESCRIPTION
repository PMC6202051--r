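Package: sercareg
Title: Micropeptide-SERCA Binding and Cardiac Calcium-Handling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of SERCA regulation by transmembrane
    micropeptides (phospholamban, DWORF) and of downstream cardiac
    calcium handling. Implements acceptor-sensitization E-FRET efficiency
    with bleed-through correction and hyperbolic binding-curve fitting,
    progressive acceptor-photobleaching FRET and stoichiometry
    classification, paced cardiomyocyte Fura-2 transient and sarcomere
    shortening kinetics, cooperative (Hill-type) oxalate-supported calcium
    uptake fitting, and echocardiographic systolic/diastolic indices with
    publication-style group statistics. Every measurement modality is
    paired with a seeded forward-model generator with known ground truth,
    so estimator accuracy is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
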