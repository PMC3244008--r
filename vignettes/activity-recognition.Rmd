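---
title: "Sequential activity classification with actihmm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential activity classification with actihmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling approach

`actihmm` classifies human physical activity from multi-channel body-worn
accelerometer recordings. The unit of classification is the *data frame*: a
512-sample window (6.7 s at the default 76.25 Hz sampling rate) advanced
with 50% overlap. Activities are of two kinds: static postures (sitting,
lying, standing), identified mainly by the projection of gravity on each
sensor axis, and dynamic gaits (walking, stair climbing, running, cycling),
identified by the periodic and impulsive structure of the signal.

A *composite activity* is a time sequence of such primitives. We model it
as a first-order Markov chain over $Q$ states with prior $\pi$ and
transition matrix $A$ ($a_{ij} \ge 0$, $\sum_j a_{ij} = 1$): the observable
Markov model (OMM). Because the primitive is never observed directly —
only the feature vector extracted from the accelerometer frame is — the
full sequential classifier is a hidden Markov model with continuous
Gaussian-mixture emissions (cHMM), $\lambda = (\pi, A, B)$ with

$$b_j(\mathbf{x}) = \sum_{m=1}^{M} c_{jm}\,
  \mathcal{N}(\mathbf{x};\, \mu_{jm}, \Sigma_{jm}), \qquad
  \sum_m c_{jm} = 1 .$$

Decoding a sentence means finding the most probable state path given the
frame sequence (the Viterbi algorithm); the sequence likelihood
$P(\mathbf{Z} \mid \lambda)$ is evaluated with the forward recursion. Both
are computed in log space with log-sum-exp, so sequences of $10^4$ frames
and 17-dimensional emissions neither overflow nor underflow.

## Features

Each frame of $c$ channels yields $3c + c(c+1)/2$ features (85 for the
ten-channel default), in fixed order:

* **DC component** — the per-channel mean; the gravity projection, which
  discriminates postures.
* **Energy** — the sum of squared DFT magnitudes of the detrended channel,
  excluding the zero-frequency bin, divided by the window length. Under
  this normalisation the energy equals the direct time-domain sum of
  squared detrended samples (Parseval), which the test suite asserts to
  `1e-9`.
* **Frequency-domain entropy** — the differential entropy of an
  Epanechnikov kernel density fitted to the magnitudes of the frame's STFT
  coefficients (one segment spanning the whole window, positive-frequency
  bins). The KDE uses Silverman's rule-of-thumb bandwidth, a 512-point
  grid spanning `[min − 3h, max + 3h]` (the defaults of
  `stats::density(kernel = "epanechnikov")`), and densities are clipped at
  `1e-12` before taking logarithms; all logarithms are natural. Entropy
  separates impact-rich gaits (walking: broad, noise-like spectra from foot
  strikes) from smooth ones (cycling: a single pedalling tone).
* **Correlation coefficients** — for every unordered channel pair
  $(i \le j)$, the dot product of the detrended channel vectors normalised
  by their Euclidean norms, i.e. the Pearson correlation. Detrending
  removes the gravity offset, which would otherwise dominate the inner
  product; this was a genuinely open reading ("normalised to their length"
  could also mean the raw cosine) and we chose the detrended form.
  Self-pairs are enumerated too — that is what makes the count 55 for ten
  channels rather than 45 — and are identically 1; they are kept so that the documented
  85-component layout is reproduced exactly and are neutralised
  by the scale-handling of every downstream consumer.

Trailing samples that do not fill a window are dropped; there is no
padding.

## Feature selection

Dimensionality is reduced by sequential search under a $k$-NN
class-separability criterion: the mean Euclidean distance from each
instance to its $k$ nearest neighbours of a *different* class divided by
the mean distance to its $k$ nearest same-class neighbours. Defaults:
$k = 1$; features standardised inside the criterion (the raw energy scale
would otherwise swamp every distance); exclusions during the floating
search accepted only on strict improvement, which guarantees termination.

`sffs_select()` implements the floating variant: after each forward
inclusion, features are conditionally excluded while that improves the
best known criterion at the reduced size. The best-per-size record is
seeded with the plain forward (SFS) pass, so the SFFS curve dominates the
SFS curve at every size by construction — our implementation makes
explicit a dominance property that does not hold for every floating-search
variant.

One caveat discovered during development and worth knowing: the ratio
criterion's raw argmax tends to collapse onto one or two dominant
features, because a subset that separates *most* class pairs enormously
outscores one that separates *all* pairs moderately. The evaluation
pipeline therefore uses the best subset of a configurable size
(`subset_size`, default 17) rather than the argmax, and reports the full criterion
curve (`tidy()`/`autoplot()` on the selection result).

## Single-frame classifiers

Probabilistic classifiers assign a frame to the class with the maximum
class-conditional density $p(\mathbf{x} \mid C_i)$ — maximum likelihood,
with no prior weighting; prior
weighting is available behind `use_prior = TRUE`. Families: naive Bayes
(independent univariate Gaussians), Gaussian mixture (`M = 1` closed form),
and Parzen (Gaussian product kernel, Silverman bandwidths per class and
dimension). Geometric classifiers are nearest mean and $k$-NN; both
standardise features with the training moments, since the Euclidean metric
is otherwise dominated by the largest-scale features.

**Covariance regularisation.** The study conditions deliberately stress
the estimators: $K = 7$ training frames per class in a 17-dimensional
space. A raw per-class covariance is then singular, and its collapsed
directions produce astronomically overconfident densities (the
log-determinant term dominates the rule, and frames are misassigned with
margins of hundreds of log-units). For $M = 1$ the class-conditional fit
therefore shrinks each class covariance towards the pooled within-class
covariance — regularised discriminant analysis — with weight
$\gamma_c = d/(d + n_c)$, plus a `1e-6·mean(diag)` diagonal floor. The
weight vanishes as the class sample grows, so large-sample fits recover
the plain sample covariance (the parameter-recovery tests run in that
regime). The identical fit is used for the cHMM emissions, preserving the
design in which the sequential classifier differs from the single-frame
GMM only by the Markov chain on top.

EM for $M > 1$ runs at most 100 iterations to relative tolerance `1e-6`
from a k-means partition under a fixed seed. Defaults use $M = 1$: the generator's classes are
unimodal by construction, so larger mixtures add parameters without
adding structure.

## Two-phase cHMM training

*First phase (supervised):* $\pi$ and $A$ are estimated by event counting
over the annotated training sentences
($a_{ij} = (n_{ij} + \delta)/(n_i + Q\delta)$), and the emissions are
fitted per state from that state's frames, exactly as above. `estimate_omm()`
defaults to pure counting ($\delta = 0$, uniform fallback rows with a
warning); the *pipeline* counts with $\delta = 0.5$, because five training
sentences do not exhibit every feasible transition and a structural zero
makes any path through the unseen transition impossible at decode time.
Emissions may be fitted from a separate $K$-frames-per-class library
(`emission_frames`), so that the training budget $K$ is shared with the
single-frame classifiers.

*Second phase (Baum-Welch):* `baum_welch_refine()` refines the model on
unlabelled data. The default mode re-estimates only $\pi$ and $A$ — the
phase exists chiefly to adapt the chain to transition behaviour absent
from training, e.g. an unexpected change of the transition regime — while
`mode = "all"` also updates the mixtures (with the covariance floor
applied every iteration). Whether a deployment should update emissions in
this phase depends on how trustworthy the supervised emission fits are;
both modes are provided, with the conservative one as default. Convergence: relative log-likelihood gain below `1e-4` or 100
iterations; the log-likelihood trace is attached to the result and is
asserted monotone in every test run.

## Spurious-frame rejection

Frames from activities outside the trained vocabulary are flagged before
decoding by thresholding the emission score
$s(\mathbf{x}) = \max_j \log b_j(\mathbf{x})$. The max over states was
chosen over a sum or a stationary-weighted sum because it is the least
prior-dependent reading of "likelihood given the emission structure"; the
alternatives differ by at most $\log Q$ and did not change behaviour in
our scenarios. The threshold is calibrated by a ROC sweep over all score
midpoints, maximising Youden's index (sensitivity + specificity), ties
towards the lower threshold, with the full curve retained for
`autoplot()`. Rejected frames are *excluded* from the decoded chain — the
chain skips them rather than dwelling — and are labelled `"SPURIOUS"` in
the output. Skip-versus-dwell was a genuinely open design point; skipping keeps the
spurious frame entirely away from the classifier and is what we document
and test.

## The synthetic-data generator

`synth_recording()` builds per-channel signals as
gravity DC profile + sinusoids (fundamental gait frequency and one
harmonic, phase-lagged across channels to create stable inter-channel
correlations) + optional exponentially decaying high-frequency bursts at
Poisson arrival times (foot impacts) + white Gaussian noise, plus two
sources of realistic variability: slow baseline drift (two random-phase
sub-0.1 Hz sinusoids per channel, emulating postural sway and attachment
shifts) and per-recording jitter of the periodic amplitudes and
frequencies (execution mannerism). The seven default specs follow the
vocabulary of the shipped transition model: three postures distinguished
by DC profiles, four gaits distinguished by fundamental frequency,
amplitude and impact content. Cycling is deliberately smooth and low-noise
so that the walking-versus-cycling entropy contrast of the feature section
holds by construction — a property the tests assert rather than assume.

The generator's difficulty was calibrated once, targeting single-frame
accuracies in the low-to-high 90s per cent — the regime in which
sequential context has errors to correct — by setting the posture drift
amplitude relative to the posture DC separations; with zero drift the
classes are perfectly separable and every ordering claim trivialises,
with excessive drift nothing is learnable from seven frames per class.
After calibration the defaults were frozen; they are study conditions, not
tuning knobs.

What the generator does **not** emulate: fuzzy postural transitions
(frames are cleanly cropped by construction), subject-to-subject anatomy,
sensor saturation and drift of the *sensor* (as opposed to posture), and
the garbage frames of a real out-of-vocabulary activity — garbage here
comes from a distinct synthetic spec family with shifted gravity profiles,
odd frequencies and heavy noise. Passing tests therefore demonstrate the
correctness and the qualitative orderings of the method on data with the
stated structure, not field performance on real recordings.

Virtual experiments: `make_virtual_experiment()` draws a state sequence of
length $T = 300$ from the OMM and samples, with replacement, one feature
vector per state from the per-class pool ($N = 30$ frames per class by
default). Garbage
injection inserts $\lfloor \rho T \rfloor$ spurious frames at uniformly
random positions ($\rho \le 1/3$, i.e. up to one spurious frame per three
genuine frames); removing the masked frames recovers the genuine sequence
exactly.

The shipped seven-state transition matrix is row-normalised by its
constructor, which guards against rounded entries; its prior is the
chain's stationary distribution.

## The evaluation pipeline and its problem sizes

`run_pipeline()` executes simulate → extract → select → train → calibrate
→ decode → evaluate, fully reproducibly from one master seed, and reports
aggregated confusion matrices and per-frame accuracies for: clean
sentences (sequential, single-frame GMM and nearest-mean on identical
frames), garbage-injected sentences without rejection, and the same
sentences with the calibrated rejector. Two accuracy views are reported
for the garbage conditions: over all frames (a spurious frame counts as an
error without a rejector, and as correct when correctly rejected) and over
genuine frames only — the latter is the clean comparison for "does
rejection restore the classifier", because with rejection enabled the
all-frames accuracy can exceed the clean run simply because rejecting
garbage is easier than classifying activities.

Default problem sizes (chosen to keep a full run around a minute while
leaving the estimators genuinely data-starved where that is the point): $Q = 7$, $T = 300$, $S = 20$ test sentences,
$P = 5$ training sentences, $K = 7$, $N = 30$, $M = 1$, SFFS to size 20
with the 17-feature subset used downstream, rejection calibrated on 60
training garbage frames, 10 garbage-injected test sentences at
$\rho = 1/3$. The acceptance script (`scripts/acceptance.R`) reruns
exactly this scenario from scratch at a caller-supplied seed.

## Numerical details in one place

* Log-space forward/Viterbi/Baum-Welch throughout; `logsumexp` guards.
* Covariance floor `1e-6·mean(diag)·I`; RDA shrinkage `d/(d+n_c)` to the
  pooled within-class covariance for class-conditional fits.
* Ties: classification and Viterbi backtracking break towards the lowest
  class/state index; threshold calibration towards the lower threshold;
  feature selection towards the lowest feature index.
* Degenerate inputs: all-zero channels yield entropy 0 with a warning;
  zero-norm channels yield correlation 0 with a warning; never-departed
  states get uniform transition rows with a warning; all-frames-rejected
  sequences raise an error rather than guessing.
* Event-counting estimation error shrinks as $1/\sqrt{T}$; with the
  shipped transition matrix the rarest state (running, stationary weight
  ≈ 0.018) dominates the worst-case entry error, so recovering every
  entry of a $Q = 7$ matrix to ±0.02 needs sequences well beyond $10^5$
  steps in unlucky draws — the package reports the max-error honestly
  rather than averaging it away.

## Known limitations

* Discrete-emission HMMs are out of scope; emissions are Gaussian
  mixtures only.
* The generator produces clean-cut state borders; no fuzzy transitions.
* Selection assumes complete cases; missing values are not handled.
* The rejection threshold is global, not per-subject.
* Branch-and-bound search is not implemented; the sequential searches are
  deliberately sub-optimal.
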