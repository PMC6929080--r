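Package: octvault
Title: Segmentation and Vault Measurement of the Cornea-Scleral Lens
    Relationship in AS-OCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic analysis of anterior-segment optical coherence
    tomography (AS-OCT) images of eyes wearing scleral contact lenses.
    Detects the outer and inner limits of the lens and the anterior corneal
    surface by edge tracing with artifact rejection and gap interpolation,
    refines each boundary with an open active contour (snake), classifies
    images by the number of visible layers, and quantifies the cornea-lens
    clearance (vault) per column under three point-correspondence paradigms
    (vertical, normal-to-tangent, nearest point) with an intuitive red-green
    heatmap rendering. Pipeline parameters can be tuned by differential
    evolution against ground-truthed data. A synthetic phantom generator
    with exact analytic ground truth makes every stage testable without
    clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
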