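Package: microniche
Title: Spatial Quantification of Tumor Microniches in Segmented Histology
Version: 0.1.0
Authors@R:
    person("Pancreas", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify tumor microniches from segmented whole-slide
    image exports of pancreatic cancer tissue: fixed-radius contact calling
    between tumor cells and annotated tissue classes, invasion-front distance
    profiles, compartment-dependent marker phenotype statistics (paired rank
    tests, Simpson diversity, hierarchical clustering), concentric stromal
    layer enrichment and intensity gradients, thresholded positive-area
    fractions, and post-count lineage-barcode clonality filtering. Includes a
    ground-truthed synthetic tissue generator so that every pipeline stage is
    testable without access to restricted clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    sp,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
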