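Package: cfitkmeans
Title: Curve-Fit Thresholded K-Means Segmentation and GLCM Trait
    Analysis for Chlorophyll-Fluorescence Canopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts wheat canopy regions from chlorophyll-fluorescence
    images with a hybrid segmenter that combines a cubic curve-fit
    dynamic elimination threshold with histogram-initialized two-cluster
    intensity K-means (CFitK-means), alongside global static, Otsu and
    four-centroid K-means baselines.  Computes a 23-trait grey-level
    cooccurrence (GLCM/Haralick) texture panel per canopy, scores
    segmentations by intersection-over-union with a random-sampling
    evaluation protocol, and analyses trait tables with correlation-range
    categorization, the Kaiser-Meyer-Olkin sampling-adequacy statistic,
    Bartlett's test of sphericity, and agglomerative clustering of traits
    under seven linkage rules.  Includes a seeded synthetic generator of
    fluorescence-like canopy scenes with ground-truth masks so the whole
    pipeline is testable without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    EBImage,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
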