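Package: laaoflow
Title: In-Silico Hemodynamic Assessment of Left Atrial Appendage Occluders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico device-related-thrombus (DRT) risk analysis
    after left atrial appendage occlusion (LAAO). Provides idealized atrium,
    appendage and occluder geometry generation, analytic pulsatile velocity
    fields with controllable intra-appendage stasis, Lagrangian platelet-cluster
    transport with drag, pressure-gradient, virtual-mass and Saffman lift
    forces, a wall-film adhesion model with a Weber-number roll/detach
    criterion, wall-shear-stress thrombogenicity indices (TAWSS, OSI, ECAP),
    pulmonary-ridge coverage geometry, and cohort-level risk descriptor tables
    with concordance scoring against clinical outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
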