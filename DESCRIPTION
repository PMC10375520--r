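Package: shiftmaps
Title: Chemical-Shift-Dependent Interaction Maps for NMR Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chemical-shift-dependent interaction maps (SIMs) and
    shift-independent interaction maps (IIMs) for molecular solids. Given a
    molecule's covalent structure and assigned experimental 1H/13C chemical
    shifts, matching local atomic environments are retrieved from a database
    of crystal structures with predicted shifts via covalent bond-graph
    descriptors, selected randomly (IIM) or under a Gaussian shift constraint
    (SIM), rigidly aligned on anchor atoms, and accumulated into per-element
    3D Gaussian density grids. Candidate crystal structures are scored by the
    overlap of their local environments with the SIM-IIM difference map and
    ranked. Includes CIF and volumetric (Gaussian cube, MRC/CCP4) input and
    output, and a synthetic small-crystal generator with a controllable
    shift-structure relationship for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
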