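Package: blebquant
Title: Morphometry of Glaucoma Drainage Implant Blebs from 3D Label Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the fluid reservoirs (blebs) that encapsulate the
    plate of a Baerveldt glaucoma drainage implant from labelled 3D
    segmentation volumes: watertight surface extraction, volume-preserving
    smoothing, mesh voxelization onto a fine isotropic grid, morphological
    closure of small inter-component gaps, compartment volumetry, bleb-complex
    height perpendicular to the implant plate, merged-bleb detection and
    large-bleb classification. Includes a synthetic orbital phantom generator
    with analytic ground truth, clinical classifiers (Hodapp-Parrish-Anderson
    visual-field bands, duction-restriction rule), and the nonparametric
    cohort statistics used to compare patients with and without diplopia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
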