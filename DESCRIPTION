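Package: ecgopt
Title: Metaheuristic-Optimized Undersampling and Classification of Unbalanced ECG Heartbeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for multiclass arrhythmia heartbeat classification from
    severely class-unbalanced single-lead ECG data. Beats are denoised (zero-phase
    Butterworth high/low-pass or db6 maximal-overlap wavelet filtering), amplitude
    normalized to [-1, 1], and segmented to 250 samples around the annotated QRS
    complex. Majority classes are undersampled by keeping the instances closest to
    the centers of per-class self-organizing-map clusters; beats are summarized by
    five statistical moments per subsegment; and a single-hidden-layer neural
    network trained by scaled conjugate gradient performs the eight-class
    classification. Differential evolution (DE/rand/1/bin) and particle swarm
    optimization jointly tune the SOM grid size, per-class undersampling
    fractions, feature subset and hidden-layer width against a cross-validated
    macro-F1 objective. Includes a seeded synthetic ECG generator, a WFDB-style
    text record dialect, macro-averaged confusion-matrix metrics, and a one-sample
    t analysis of repeated runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
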