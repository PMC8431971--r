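Package: nbfixr
Title: Pair-Specific Lennard-Jones Corrections and Binding-Site Analysis for
    Cation-Sulfur Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for parameterizing and analysing cation-thioether
    interactions in fixed-charge force fields of the CHARMM dialect.
    Fits pair-specific Lennard-Jones overrides (NBFIX) so that a rigid-dimer
    molecular-mechanics energy curve matches a reference ion-sulfur
    potential-energy scan; mines protein structures for Na+ contacts with
    methionine and cysteine sulfur atoms under resolution and distance
    filters; computes reversal potentials and potassium diffusion-potential
    buffer recipes for coupling-stoichiometry assays of secondary
    transporters; and provides distance, dissociation-event, histogram and
    occupancy-grid analyses of binding-site trajectories, with
    seed-deterministic synthetic generators for reference curves, structure
    fixtures and trajectories.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
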