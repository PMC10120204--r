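Package: polypembed
Title: Few-Shot Colorectal Polyp Image Classification by Deep Metric Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A few-shot learning pipeline for classifying colorectal polyp
    images into surface-pattern classes (NICE-style spotted/homogeneous
    versus tubular/branched) when only a single image per polyp is
    available. An image encoder is trained with a contrastive triplet
    loss (margin 20, l2 metric) to map 224x224 RGB crops into a
    64-dimensional embedding space in which simple discriminators
    (1-nearest-neighbour, nearest-centroid, RBF-kernel SVM) classify new
    polyps. Includes endoscopy-specific augmentation (flips, photometric
    jitter, gaussian noise, specular-highlight detection and grafting),
    three triplet-mining regimes (class-supervised, multilabel
    class-disjoint, self-supervised augmented-view), keyframe selection
    from video by keypoint matching and sharpness, polyp-disjoint
    repeated-split evaluation with 90 percent confidence intervals, and
    fully synthetic data generators so every stage can be exercised
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    cluster,
    withr
Config/testthat/edition: 3
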