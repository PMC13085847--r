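Package: strokeflow
Title: Microvascular Flowmetry, Capillary Constriction Morphometry and
    Stereology for Experimental Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for mouse stroke microcirculation studies:
    laser speckle contrast imaging flowmetry (spatial contrast, nonlinear
    inversion to inverse correlation times, relative cerebral blood flow and
    percent-change maps, ROI statistics), rule-based detection of pericyte-
    associated capillary constrictions on diameter-annotated vessel skeletons
    with disector-frame stereological densities, peri-microvascular stain
    densitometry on semi-quantitative scales, edema-corrected (Swanson)
    infarct volumetry from serial sections, systolic blood pressure
    extraction from tail-cuff pressure/flow traces, and the accompanying
    nonparametric statistical workflow. Includes seeded synthetic-data
    generators with known ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
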