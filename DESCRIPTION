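Package: primateFaces
Title: Face Recognition and Social Network Analysis for Primate Video Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual identification of primates (developed around rhesus
    macaques) from face images using masked, block-wise uniform local binary
    pattern (LBP) histograms with nearest-neighbour, diagonal linear
    discriminant and linear support vector machine classifiers, optionally
    after principal component reduction. Includes the combination
    face-validation geometry (eye and nose sub-region checks on candidate
    face crops), landmark-based face alignment, detection evaluation
    metrics, and downstream social-proximity analysis: windowed sighting
    aggregation, simple-ratio association matrices, Mantel matrix
    correlation, and group-membership permutation tests for preferred
    associations. A seeded synthetic-data generator produces face images
    with controllable identity signal and nuisance conditions, detection
    frames with ground truth, and sighting streams with known association
    structure, so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
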