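Package: SpheroidProfiler
Title: Quantitative and Spatial Depth Profiling of Tumour Spheroid
    Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments nuclei, cells and the whole-spheroid footprint in
    multi-channel fluorescence images of tumour spheroid equatorial
    sections, measures each object's distance to the spheroid surface,
    and builds depth-binned profiles of hypoxia staining intensity
    (pimonidazole), dead-cell fraction (DRAQ7), immune-cell infiltration
    (labelled PBMCs) and FUCCI cell-cycle reporter ratios (mKO2/mAG).
    Includes a synthetic spheroid phantom generator with per-object
    ground truth so every stage of the pipeline can be validated without
    microscopy data, and a config-driven end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
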