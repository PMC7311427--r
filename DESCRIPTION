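Package: cowpipe
Title: Automated Labeling and Variant Classification of the Circle of Willis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated image-processing pipeline for time-of-flight
    magnetic-resonance-angiography-like volumes of the cerebral vasculature.
    The pipeline segments bright tubular vessels with adaptive k-means
    initialization refined by a two-phase (strict/relaxed) Chan-Vese active
    contour, reduces the masks to one-voxel-thick skeletons with
    topology-preserving 3-D thinning, converts skeletons to vascular graphs,
    and labels the end-basilar and left/right M1/A1 branching points of the
    Circle of Willis against an atlas using geometric node scores. Failure of
    symmetric M1/A1 identification classifies A1-segment variants (aplasia),
    and bilateral radius/intensity/tortuosity features score hypoplasia. A
    synthetic vascular phantom generator with known ground truth supports
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
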