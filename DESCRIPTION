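Package: frameTriage
Title: Machine-Learning Triage of Serial Crystallography Detector Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying X-ray free-electron-laser (XFEL) detector
    frames as good or bad, for example to remove frames carrying detector
    gain-switching artefacts before crystallographic indexing. Parses
    CrystFEL-format detector geometry, reads multi-event HDF5 frame stacks,
    auto-labels frames from the inflection points of a polynomial fit to a
    region-of-interest intensity profile, trains and evaluates four classical
    classifiers (logistic regression, K-nearest neighbours, decision tree,
    random forest) on ROI pixel intensities, reports confusion-matrix
    diagnostics, and batch-sorts large frame stores into good/bad event lists.
    Includes a synthetic frame generator emulating a diffuse water ring,
    Bragg-like spots and a per-panel miscalibration artefact for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    rhdf5,
    randomForest,
    rpart,
    glmnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
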