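Package: sellabench
Title: Evaluation of Human and AI-Assisted Sella Annotations on Endoscopic Images
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring polygon annotations of the sella turcica on
    endoscopic pituitary-surgery images against an expert-consensus ground
    truth. Polygons are rasterized to binary masks (pixel-centre, even-odd
    fill); per-annotation DICE scores, union-normalised false-positive and
    false-negative area fractions and centroid-inclusion flags are computed;
    expertise subgroups are compared across an unassisted and an AI-assisted
    annotation round with exact paired statistics (Wilcoxon signed-rank,
    Fisher's exact, exact McNemar); multi-rater agreement heat maps are
    rendered with ground-truth and AI contour overlays. A seeded synthetic
    study generator emulates the full design (4 expertise groups x 6
    annotators x 6 images x 2 rounds) so every pipeline stage is testable
    without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
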