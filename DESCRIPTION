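Package: poremetrics
Title: Quantitative Analysis of Membrane Pore Formation by Pore-Forming
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for atomistic molecular-dynamics studies of
    pore-forming proteins such as the gasdermin-D N-terminal domain.
    Implements membrane edge-tension estimation from pressure-tensor time
    series with block-averaged errors, dual-cutoff lipid-protein contact
    residence and bridging-lipid statistics, complete-crossing ion
    permeation counting and water-column continuity, pore and membrane
    geometry observables (inscribed-disc pore radius, crown deformation
    profiles, hairpin tilt, ring circularity and arc-crack detection,
    membrane thinning), Eisenberg-scale hydrophobicity scoring of
    pore-facing residues, and asymmetric plasma-membrane composition
    planning with counterion accounting.  Seeded synthetic-system
    generators provide every input class with recorded ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
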