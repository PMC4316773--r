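Package: scenespace
Title: Representational Similarity Analysis of Scene Spaces from Vision
    Models, Brain Patterns, and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and compares scene-by-scene similarity spaces from three
    measurement domains: computer-vision image descriptors (GIST, histogram of
    oriented gradients pyramids, self-similarity descriptors, dense SIFT
    variants and hue histograms quantized with bag-of-visual-words codebooks,
    geometric-class probability maps, and attribute classifier scores with
    exponentiated-variance reweighting), trial-level voxel patterns reduced to
    one response pattern per scene within a region of interest, and pairwise
    similarity ratings collected in crowd-sourced tasks.  Second-order analysis
    correlates Fisher-transformed similarity spaces across methods, ranks
    candidate models against a neural target, partitions variance with
    ordered-block hierarchical regression, and tests model-fit differences with
    a pair-resampling bootstrap.  A synthetic-data module generates stimuli,
    attribute tables, voxel time courses with a known embedded similarity
    structure, and right-skewed rating tables with catch trials, so that the
    whole pipeline can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
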