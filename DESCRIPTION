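Package: dyadinfer
Title: Synchrony-Weighted Active Inference for Dyadic Category Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how two agents converge on shared category judgments
    through joint action. Implements a dual-layer Bayesian partner model
    (conjugate Beta-Bernoulli counting plus an exponential-moving-average
    refinement), free-energy action selection with a gaze-synchrony-weighted
    agreement term, dynamic-time-warping (DTW) gaze synchrony indices
    computed from paired pupil-velocity streams, a synthetic dyad and gaze
    simulator emulating a VR object-categorization task with a bot partner,
    and evaluation utilities (partner/self prediction accuracy, precision,
    recall, F1, AUC, MCC, post hoc z-test power, trial-wise trajectory
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
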