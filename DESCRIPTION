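Package: membramech
Title: Mechanics and Structure of Lipid Mono- and Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis suite for the biophysical characterization of lipid
    membranes. Computes structural and dynamic observables from coordinate
    frame series (Voronoi area per lipid, membrane thickness, leaflet
    interdigitation, lateral diffusion via the Einstein relation), mechanical
    moduli by the real-space fluctuation method (bending rigidity from lipid
    splay, tilt modulus from lipid tilt) and from thickness fluctuations
    (area compressibility), hydrophobic defect exposure by occupancy-grid and
    sphere-probe analysis, Langmuir isotherm thermodynamics (surface
    elasticity, excess free energy of mixing), and flicker-noise spectroscopy
    of giant unilamellar vesicle contours. Deterministic synthetic-data
    generators provide ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
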