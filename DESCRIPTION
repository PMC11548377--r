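Package: vbimap
Title: Mapping Lake Aquatic Vegetation and Algal Blooms with Vegetation and Bloom Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping submerged aquatic vegetation (SAV),
    floating/emergent aquatic vegetation (FEAV), algal blooms (AB) and open
    water (OW) in shallow lakes from multiband surface-reflectance imagery.
    Implements the vegetation and bloom indices (VBI) workflow: per-pixel
    spectral indices (tasseled-cap-wetness-based AVI, floating algae index
    FAI, NDVI, NDWI), a three-step decision-tree classifier with per-scene
    AVI threshold calibration against open water, confusion-matrix accuracy
    assessment (overall accuracy, Cohen's kappa), per-class coverage time
    series, and ordinary least-squares analysis of coverage against
    water-quality drivers (TP, TN, depth/transparency ratio). Includes
    synthetic scene and water-quality generators with known ground truth so
    the whole pipeline can be exercised and validated at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
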