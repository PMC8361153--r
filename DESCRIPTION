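Package: serialface
Title: Superimposition and Distance Analysis of Serial 3D Facial Surfaces
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing facial change in growing individuals from
    serial 3D facial surface meshes. Provides region-constrained rigid
    superimposition by point-to-plane iterative closest point (ICP) on
    anatomically defined reference areas, exact signed point-to-surface
    distance maps, mean absolute distance (MAD) summaries at landmark-seeded
    100-vertex measurement patches, comparison of superimposition references
    against a gold-standard alignment, reproducibility differences between
    repeated runs, the accompanying nonparametric statistics (Kruskal-Wallis
    omnibus test with Dunn-Bonferroni post hoc pairwise comparisons, normality
    screening), and a synthetic longitudinal face generator with known
    ground-truth transforms and growth fields for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nortest,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
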