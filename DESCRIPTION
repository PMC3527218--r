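Package: barrelfield
Title: 3D Reconstruction, Standardization and Neuron Registration for the
    Rat Vibrissal Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the three-dimensional geometry of the rat
    vibrissal (barrel) cortex from tangential section images, to build a
    standardized average cortex model by rigid (generalized Procrustes)
    registration of multiple animals, to quantify the variability of
    anatomical landmarks, to parameterize the somatotopic layout with
    second-order polynomial maps, and to register single-neuron
    morphologies (SWC) into the standard model with rigid transformations
    and stepwise linear scaling along the cortical column axis. Includes a
    synthetic-data module that generates ground-truth barrel fields,
    rendered section-image stacks and neuron morphologies so that every
    stage of the pipeline can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
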