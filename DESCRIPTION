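Package: mdpsoseg
Title: Adaptive Multidimensional Particle-Swarm Clustering for Multi-Modal MRI Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustering-based brain-lesion segmentation of co-registered
    multi-modal MRI (FLAIR, T1CE, T1, T2) using a multidimensional particle
    swarm optimizer (MDPSO) that searches jointly over the number of clusters
    and centroid placements in a joint spatial-intensity feature space.
    Includes percentile intensity normalization, SLIC superpixel
    pre-aggregation for volumes, a randomized Gabor filter bank with
    k-means-based filter selection, voxel- and cluster-level descriptors,
    random-forest voxel classification, segmentation evaluation metrics
    (ASA, a lesion-focused Dice-like ASA variant, confusion-matrix metrics,
    95th-percentile Hausdorff distance, box-counting fractal dimension),
    distance-weight calibration by sequential model-based optimization,
    and a synthetic multi-modal phantom generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
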