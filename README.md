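# actihmm

Classification of human physical activity — static postures (sitting,
lying, standing) and dynamic gaits (walking, stair climbing, running,
cycling) — from multi-channel body-worn accelerometer recordings. The
package is aimed at movement-analysis and wearable-sensing researchers who
want a complete, reproducible reference chain: windowed feature
extraction, floating feature selection, single-frame classifiers, and a
sequential classifier built on a hidden Markov model, together with a
synthetic-data generator that makes the whole chain testable without any
proprietary recordings.

## The model

Raw signals are cut into 50%-overlapping 512-sample frames (6.7 s at
76.25 Hz). Each ten-channel frame yields an 85-component feature vector:
per-channel mean (DC, the gravity projection), spectral energy,
frequency-domain entropy (differential entropy of an Epanechnikov kernel
density fitted to the STFT coefficient magnitudes), and the 55
correlation coefficients of all unordered channel pairs.

A composite activity is modelled as a first-order Markov chain over
Q activity primitives with prior π and transition matrix A (rows summing
to 1). The sequential classifier is a continuous-emission hidden Markov
model λ = (π, A, B) whose state emissions are Gaussian mixtures

    b_j(x) = Σ_m c_jm N(x; μ_jm, Σ_jm),   Σ_m c_jm = 1 .

Training is two-phase: supervised event counting for (π, A) plus per-state
class-conditional Gaussian fits for B, optionally followed by Baum–Welch
refinement on unlabelled data (by default re-estimating the transition
parameters only). Sentences are decoded with the Viterbi algorithm in log
space. Out-of-vocabulary ("spurious") frames are flagged before decoding
by thresholding the emission score max_j log b_j(x); the threshold is
calibrated by a ROC sweep maximising Youden's index.

## Worked example

Simulate a labelled frame library, train the sequential classifier, and
decode a fresh 150-frame composite activity:

```r
library(actihmm)

specs <- default_activity_specs()                    # 7 activities, 10 channels
lib <- build_frame_library(specs, frames_per_class = 10, seed = 42)
dim(lib)
#> [1] 70 87            # 70 labelled frames x (label + frame_start + 85 features)

om <- seven_activity_omm()                           # shipped transition model
train <- lapply(1:2, function(i) make_virtual_experiment(om, lib, 150, seed = i))
model <- first_phase_train(train, smoothing = 0.5,
                           emission_frames = lib, labels = om$labels)
model
#> <chmm> 7 states, d = 85, M = 1

test <- make_virtual_experiment(om, lib, 150, seed = 99)
decoded <- classify_sequence(model, test)
confusion_matrix(test$label, decoded, labels = om$labels)
#> <confusion_matrix> 7 classes, 150 outcomes, accuracy 1.0000
#>           estimate
#> truth      lying cycling climbing walking running sitting standing
#>   lying       51       0        0       0       0       0        0
#>   cycling      0       6        0       0       0       0        0
#>   climbing     0       0        6       0       0       0        0
#>   walking      0       0        0      34       0       0        0
#>   running      0       0        0       0       1       0        0
#>   sitting      0       0        0       0       0      26        0
#>   standing     0       0        0       0       0       0       26
```

Row counts mirror the chain's stationary distribution (lying and walking
dominate; running is rare). With all 85 features and ten frames per class
this demo is easy; the evaluation pipeline below runs the deliberately
stressed study conditions — 7 training frames per class in a 17-feature
subspace chosen by floating selection — where single-frame classifiers
err and the Markov chain visibly helps:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> <activity_pipeline_report>
#>                    condition accuracy n_frames
#>             clean_sequential   0.9618     6000
#>             clean_single_gmm   0.9468     6000
#>              clean_single_nm   0.8575     6000
#>            garbage_no_reject   0.7212     4000
#>          garbage_with_reject   0.9740     4000
#>    garbage_no_reject_genuine   0.9617     3000
#>  garbage_with_reject_genuine   0.9653     3000
#> rejection on held-out garbage: sensitivity 1.000, specificity 1.000
```

The three orderings the package is built to demonstrate are visible in
that table: the sequential classifier beats the single-frame GMM on
identical frames; 1:3 garbage injection collapses accuracy when nothing is
rejected; and the calibrated likelihood threshold restores genuine-frame
accuracy to within a fraction of a point of the clean run.

Result objects have broom-style `tidy()`/`glance()` methods and
`autoplot()` (confusion heat map, selection criterion curve, rejection
ROC). Models serialise to JSON via `save_model()`/`load_model()`, and a
thin command-line interface over the same functions ships in
`inst/cli/actihmm.R` (subcommands `simulate`, `extract-features`,
`select`, `train-single`, `train-chmm`, `refine-chmm`, `calibrate-reject`,
`decode`, `evaluate`, `run`).

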