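Package: rtdcm
Title: Near Real-Time Dynamic Causal Modeling for Connectivity-Based
    Neurofeedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative modeling and variational Bayesian inversion of
    bilinear dynamic causal models (DCM) for fMRI, tailored to near
    real-time connectivity-based neurofeedback. Simulates BOLD signal
    from a four-region visual-attention network through a
    balloon-Windkessel hemodynamic model, inverts competing network
    architectures under an iteration budget, emits a log Bayes factor
    feedback signal within a streaming pipeline (causal drift removal,
    despiking, smoothing, sliding-window model comparison), and provides
    the offline evaluation statistics (sign test with normal
    approximation, random-effects Bayesian model selection exceedance
    probabilities, permutation slope tests, Jarque-Bera normality check,
    percent-signal-change and contrast-to-noise baselines). A synthetic
    data module generates ground-truth sessions, including small 4D
    volumes with region masks, so every stage is testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
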