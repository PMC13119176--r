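Package: lesionAug
Title: Category-Aware Lesion-Level Copy-Paste Augmentation for Long-Tailed
    Plant Disease Detection Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reshapes the class distribution of long-tailed object-detection
    datasets of plant-disease lesions by category-aware, lesion-level
    copy-paste augmentation. Object crops of rare (tail) classes are harvested
    into a class-indexed bank, pasted onto diverse backgrounds at uniformly
    sampled positions and jittered scales, passed through a multi-stage
    environment simulator (luminance perturbation, fog/rain/blur weather
    effects, physical occlusion with per-box visibility accounting), and
    screened by a teacher detector in an accept-reject step that keeps only
    samples with consistent localization and confident class evidence.
    Includes distribution diagnostics (imbalance ratio, log-scale dispersion,
    effective-category coverage, effective-sample proportion, center and scale
    histograms), YOLO-format dataset input/output with stratified splitting, a
    procedural synthetic leaf/lesion dataset generator with an oracle teacher
    for end-to-end testing, and closed-form utilities for gradient-weighted
    saliency response maps and multi-scale convolution FLOPs estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Classification, Visualization
RoxygenNote: 7.3.3
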