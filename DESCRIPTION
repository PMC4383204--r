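Package: cav3d
Title: 3D Serial-Section Morphometry of Vessel Neointima
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a 3D volume from serial 2D histology sections,
    rigidly aligns the stack, segments lumen and neointima from seed
    annotations, extracts the vessel centerline and re-slices the volume
    perpendicular to the vessel axis, and quantifies chronic allograft
    vasculopathy through the per-section Neointimal Index (NI) and the
    segment-level Neointimal Volume Index (NVI). Includes a synthetic
    vessel-phantom generator with analytic ground truth for validating
    every stage (oblique-sectioning bias, registration recovery,
    segmentation accuracy, volumetric consistency), and a simple
    channel-arithmetic virtual angiography renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
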