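Package: fthnet
Title: Transformer-Hypernetwork Quality Scoring for Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: No-reference quality assessment for colour fundus photographs.
    Implements a windowed-attention transformer backbone, a multi-scale
    distortion-perception branch, and a hypernetwork that generates the
    weights and biases of a five-layer scoring head, regressing a continuous
    0-100 mean opinion score (MOS). Ships the dataset protocol (seniority
    weighted MOS aggregation, Good/Usable/Reject level mapping, rater
    consistency statistics, 80/5/15 splits), a synthetic fundus phantom
    generator with parameterised clinical degradations and a six-rater noise
    model, evaluation metrics (SRCC/PLCC/RMSE, three-level confusion), a
    CPU training pipeline with Adam and a warmup/linear-annealing schedule,
    and a parameter-count calibration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    withr,
    jsonlite,
    yaml,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
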