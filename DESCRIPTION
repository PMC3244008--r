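Package: actihmm
Title: Sequential Classification of Physical Activity from Body-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human physical activity (postures and gaits) from
    multi-channel accelerometer recordings. Raw signals are cut into
    50%-overlapping windows from which time- and frequency-domain features
    are extracted (per-channel mean, energy, spectral entropy via
    Epanechnikov kernel density estimation, and inter-channel correlations).
    Feature subsets are chosen by sequential floating forward selection
    under a k-nearest-neighbour class-separability criterion. Single-frame
    probabilistic and geometric classifiers are provided alongside a
    sequential classifier built on a hidden Markov model with Gaussian
    mixture emissions, trained in two phases (supervised event counting
    plus optional Baum-Welch refinement), decoded by the Viterbi algorithm,
    and protected against out-of-vocabulary frames by likelihood-threshold
    rejection calibrated through ROC analysis. A simulator of composite
    activities driven by an observable Markov model generates labelled
    virtual experiments for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
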