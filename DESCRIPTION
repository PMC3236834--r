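Package: ndlesion
Title: Density-Based Skin Lesion Border Detection in Dermoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated delineation of pigmented skin lesion borders in
    dermoscopy-style RGB images by density-based clustering. Provides a
    reference DBSCAN with pluggable pixel metrics, a boundary-accelerated
    variant (FDBLD) that tracks cluster boundaries as unions of convex hulls
    and fires region queries only for leading points near the boundary, and
    a joint normalized colour-spatial pixel distance that lets the clusterer
    work directly on colour images without a binarisation step. Includes
    intermeans automatic thresholding for the binary baseline pipeline,
    lesion-cluster selection heuristics, segmentation quality metrics
    (precision, recall, XOR border error), and a seeded generator of
    dermoscopy-like phantom images with exact ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    polyclip,
    sp,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
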