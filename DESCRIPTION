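Package: lesionasym
Title: Shape-Asymmetry Features and Feedforward Network Classification of
    Skin Lesion Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the asymmetry of segmented skin lesions from binary
    masks using four shape-asymmetry indices (principal-axis fold overlap,
    minimum fold overlap, quadrant asymmetry, and projection-histogram
    correlation) and classifies lesions (nevus, melanoma, dysplastic nevus)
    with a single-hidden-layer feedforward network trained by
    Levenberg-Marquardt least squares with validation-based early stopping.
    Includes confusion-matrix performance metrics, a seeded synthetic
    lesion-shape generator based on radial harmonics, stratified data
    splitting, and an architecture-sweep harness over dataset combinations
    and hidden-layer sizes, with SVM and k-nearest-neighbour comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
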