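Package: gazefilter
Title: Uncertainty-Driven Scanpath Simulation with Particle-Filter Object
    Segmentation in Dynamic Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates human-like gaze behavior (scanpaths) on dynamic scenes
    by interconnecting two recursive processes: a particle filter that
    maintains a belief over the object segmentation of each video frame and
    derives a boundary-entropy uncertainty map from it, and a multi-option
    drift-diffusion decision process in which segmented objects accumulate
    evidence (a product of visual sensitivity, scene saliency, and
    segmentation uncertainty) to become the next saccade target. Foveating an
    object feeds a high-confidence prompted segmentation of that object back
    into the filter, resolving uncertainty at the gaze position and thereby
    driving exploration without an explicit inhibition-of-return mechanism.
    Includes a parametric synthetic-scene generator providing ground-truth
    labels, optical flow, saliency and noisy segmentation cues; discounted-IoU
    object tracking; scanpath evaluation statistics (foveation categories,
    Kolmogorov-Smirnov distances, log-normal and gamma fits, relative
    saccade-angle profiles); and a grid-search driver for parameter fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    fitdistrplus,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
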