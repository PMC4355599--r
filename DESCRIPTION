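Package: echograde
Title: Tumor Grading from 3-D Breast Ultrasound Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided grading of breast-cancer lesions in 3-D ultrasound
    volumes. Quantifies 44 features per lesion from a gray-level volume and a
    co-registered binary mask: 24 gray-level co-occurrence (Haralick) texture
    statistics over four displacement vectors, 6 morphological descriptors
    (volume, mesh surface area, classical and discrete compactness, radius
    statistics), 9 ellipsoid-fitting descriptors (axis/surface/volume ratios and
    residual-region counts with angularity), and 5 posterior acoustic features
    measured in a distance-transform-shrunken region beneath the lesion.
    Low- versus high-grade classification uses a class-weighted soft-margin RBF
    support vector machine whose feature subset and hyperparameters are selected
    by a genetic algorithm maximising 0.8*(sensitivity*specificity) + 0.2/k,
    evaluated by stratified tenfold cross-validation. A phantom generator
    produces synthetic speckle volumes with controllable shape, texture and
    posterior-acoustic structure for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    e1071,
    nortest,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
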