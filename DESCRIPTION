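Package: emgadapt
Title: Adaptive EMG Pattern Recognition Across Repeated Uses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating surface-electromyography (EMG)
    pattern-recognition pipelines that stay accurate across repeated uses,
    when electrode donning and doffing shifts the feature distribution
    between sessions. Provides sliding-window segmentation and the fourteen
    classic time-, frequency- and wavelet-domain EMG features; scatter-matrix
    (J3) separability scoring with sequential forward selection and particle
    swarm optimisation over feature dimensions; four linear-SVM classifier
    strategies including batch-incremental adaptation and instance-transfer
    (TrAdaBoost) reweighting; a synthetic multi-day EMG generator with a
    controllable electrode-shift model; and a reverse five-fold benchmark
    protocol with accuracy and timing summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
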