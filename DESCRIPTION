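Package: trochlea
Title: Talar Trochlea Morphometry from Triangulated Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the regional radii of curvature of the talar trochlea from
    CT-derived surface meshes. Builds a standardized anatomical coordinate system
    from seven digitized landmarks, cuts coronal and near-sagittal section curves,
    measures six regional radii (anteromedial, anterolateral, posteromedial,
    posterolateral, mid-anterior, mid-posterior) by three-point circumcircles, and
    fits a least-squares cylinder to the separated trochlear surface. Includes a
    synthetic trochlea generator with analytically known radii for validation, and
    a summary-statistics layer (pooled t, one-way ANOVA, LSD pairwise comparisons,
    count-weighted pooling) that operates directly on published (n, mean, SD)
    triplets as well as on raw per-specimen records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
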