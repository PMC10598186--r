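Package: bronchiq
Title: Airway Tree Quantification from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the bronchial tree from a chest CT volume and a
    binary airway lumen segmentation. Cleans the mask, derives a rooted
    acyclic centreline graph by topology-preserving 3D thinning, labels
    lung lobes and airway generations, measures lumen diameters on
    spline-resampled perpendicular cross-sections with a full-width
    half-maximum edge-cued ellipse caliper, and summarises per-patient
    biomarkers of traction bronchiectasis (intersegmental tapering,
    segmental tortuosity, total segment count) over a configurable
    generation window. A synthetic tube-tree phantom generator with
    analytic ground truth supports end-to-end validation without
    clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
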