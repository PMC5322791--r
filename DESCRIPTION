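Package: branchmorph
Title: Skeleton-Based Morphometrics of Branching Thalli from 2D Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated morphometric analysis of 2D images of
    complex-shaped branching organisms such as thalloid liverworts.
    Binarizes raster images (Otsu thresholding, morphological cleanup),
    reduces the specimen to a single-pixel skeleton by Zhang-Suen thinning,
    classifies junctions and terminals, builds a skeleton graph traversed by
    depth-first search, and quantifies six morphological variables: junction
    thickness, branch thickness, terminal thickness, branch length, branch
    angle and terminal spacing, via the Euclidean distance transform. A
    statistics layer discriminates predefined groups with per-variable ANOVA
    and Tukey pairwise comparisons, Pearson correlation, MANOVA (Wilks) and
    canonical discriminant analysis with resubstitution classification. A
    synthetic thallus generator with exact ground truth supports systematic
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
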