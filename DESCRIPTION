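Package: pallor
Title: Conjunctival Pallor Image Analysis for Anemia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive anemia screening from eye-conjunctiva photographs.
    Segments the palpebral conjunctiva by color-based K-means clustering in
    the CIELAB (a*, b*) plane, extracts seven statistical and color features
    (mean intensity, red/green ratio and difference, intensity standard
    deviation, histogram entropy, high-hue ratio, red-pixel percentage),
    grades subjects into anemic / moderately anemic / normal classes against
    a hemoglobin gold standard, and classifies feature vectors with a small
    multilayer perceptron. Includes a synthetic eye-image generator with
    ground-truth masks and lighting-condition augmentation for fully
    reproducible end-to-end evaluation, plus grid-based geospatial prevalence
    aggregation of screening records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    EBImage
Config/testthat/edition: 3
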