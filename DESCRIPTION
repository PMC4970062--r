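Package: kiwigrade
Title: Single-Camera Shape Grading of Kiwifruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Grades kiwifruit into UNECE FFV-46 shape classes from a single
    top-view camera image and a weight reading. Segments the fruit silhouette
    (Otsu thresholding, connected-component area filtering), extracts length,
    maximum equatorial diameter and projected area via a minimal bounding
    rectangle with millimetre calibration from coordinate paper, estimates the
    hidden minimum equatorial diameter and the fruit volume with linear models
    selected by stepwise multiple linear regression, assigns grade classes
    from weight and the diameter ratio, and improves the grade assignment with
    a linear-discriminant reclassification in shape-ratio space. Includes a
    synthetic-data generator producing fruit images with known ground truth
    and morphometric populations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
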