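Package: oceStrain
Title: Phase-Sensitive Optical Coherence Elastography Strain Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of dynamic axial strain in corneal
    tissue from phase-sensitive optical coherence elastography (OCE).
    Provides a complex OCT speckle-volume phantom with prescribed
    depth- and time-dependent deformation fields (osmotic swelling and
    deswelling, cross-linking-like anterior shrinkage), the
    amplitude-weighted complex cross-correlation estimator of axial
    displacement and strain, corneal surface detection and
    depth-registered regional averaging, cumulative regional strain
    time series and depth-time strain maps, and segmented linear
    regression with paired and unpaired slope comparisons between
    treatment groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
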