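Package: teacanopy
Title: UAV Canopy Segmentation, Spectral Indices, and Physiological
    Regression for Tea Plantations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline linking drone imagery of tea plantations to
    plant physiology. Generates seeded synthetic plantation scenes with known
    canopy masks and planted physiological relations; segments the tea canopy
    with SLIC superpixels, Otsu thresholds on vegetation-index means, dual
    limits and manual overrides; computes 19 colour indices and 50
    multispectral indices over the canopy; ranks indices against leaf area
    index (LAI), the photochemical reflectance index (PRI) and the quantum
    yield of photosystem II (PhiPSII) by Pearson correlation, minimum
    redundancy maximum relevance and gray relational analysis; sweeps eight
    regressors over incrementally added ranked features with three-fold
    cross-validation; and applies a 95-percent-of-best parsimony rule plus
    field-style descriptive and inferential statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    glmnet,
    rpart,
    ranger,
    xgboost,
    mixOmics,
    igraph,
    car,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
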