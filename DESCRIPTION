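Package: contourdev
Title: Distance-Deviation Analysis of Contouring Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies variability between closed delineation contours drawn
    on slices of a medical image volume. Each contour set is converted into a
    signed Euclidean distance image; per-voxel deviation of distances across
    observers (absolute difference for a pair, RMS against a reference, or
    standard deviation without one) yields deviation maps, per-angle maximal
    deviation profiles, and scalar summaries (maximal and mean distance
    deviation, the former equal to the Hausdorff distance for two contours).
    Includes polygon rasterization with even-odd semantics, HSV overlay and
    angular heatmap rendering, synthetic contour generators for testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
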