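---
title: "Methods: the bcichain decoding stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bcichain decoding stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bcichain` implements the translation layer of a thought-controlled
computing environment: a four-class motor-imagery (MI) decoder, a P300
matrix-speller decoder, and a finite-state controller that maps the four
decoded commands onto application actions. This vignette documents the
models, the parameters that matter, the numerical conventions, and what the
synthetic-data tests do and do not establish.

## Domain model and data contracts

A recording is a channels × samples matrix in microvolts with a sampling
rate, unique 10-10/10-20 channel labels, and an event table. Sample indices
are 0-based and epoch windows are half-open `[start, end)`: an epoch spans
exactly `floor((t_end − t_start) · fs)` samples starting at the event
sample. This floor rule is load-bearing: at 240 Hz a 0–667 ms post-stimulus
window gives exactly 160 samples, and decimation by `floor(fs/20) = 12`
leaves 14 samples per channel, hence 64 × 14 = 896-dimensional speller
vectors. 240 Hz is the package default for the speller configuration
because it is the unique round sampling rate under which the 0–667 ms
window and cutoff-based decimation jointly produce 14 samples; every
operation nevertheless takes `fs` as data, not as an assumption.

Cleaning discards whole recordings that miss a required electrode or
contain non-finite samples, and reports what it removed; it never repairs
data. Epochs whose window would cross a recording boundary are dropped and
counted, not truncated.

## Spatial filtering

The common average reference subtracts the instantaneous channel mean; the
surface Laplacian subtracts the unweighted mean of each electrode's
neighbors — the 4 nearest electrodes ("small") or the 4 next-nearest
("large") by Euclidean distance in the montage's schematic 2-D coordinates.
Unweighted neighbor means are the default because that is the plain
definition of the re-reference; inverse-distance weighting is available as
a flag. Edge electrodes with missing neighbors fall back to the available
subset so the channel count (and hence the feature-vector length) is
preserved. The default chain order is CAR first, then the small Laplacian;
whether the two are applied jointly or alternatively is an experimental
choice, so both stages are independently toggleable. Both filters are
linear, CAR is a projection, and the Laplacian annihilates common-mode
signals — all property-tested.

The built-in montage is a schematic 10-10 grid of 64 electrodes (62 for the
MI default, dropping the extreme midline sites). Coordinates are for
neighbor determination only, not for source modeling.

## The feature bank

Per channel and epoch, in fixed order (17 features at the default AR
order): μ and β Welch band power, Hjorth activity/mobility/complexity,
AR(4) coefficients, Higuchi fractal dimension, approximate entropy, sample
entropy, permutation entropy, skewness, excess kurtosis, variance and
standard deviation. Conventions that affect values:

* **Welch PSD** — Hann window, 1 s segments, 50% overlap, segment means
  removed, one-sided density; band power integrates bins whose centers fall
  inside the band with the trapezoidal rule. The method is named by the
  chain; these parameters are the package's own standard choices.
* **Hjorth derivative** — the per-sample first difference with no `fs`
  scaling, so a sinusoid at frequency `f` has mobility ≈ `2πf/fs`. Activity
  uses the same N−1 variance as the reported variance feature, for internal
  consistency.
* **AR estimator** — Burg, the standard for short EEG segments (no
  windowing loss); Yule-Walker is available for cross-checks. Coefficients
  are reported in lag order under the convention
  `x_t = Σ φ_i x_{t−i} + ε_t`.
* **Fractal dimension** — the box-counting limit is a definition, not an
  algorithm; the estimator is Higuchi's curve-length method (kmax 10),
  clipped with a warning to the valid planar range [1, 2].
* **Approximate entropy** — the standard Pincus form
  `φ^m(r) − φ^(m+1)(r)` with self-matches included. The compact
  summation sometimes printed for ApEn is not computable as written; the
  Pincus form is the measure it abbreviates, and our implementation is
  pinned to an exhaustive template-counting oracle in the tests.
* **Sample entropy** — `−log(A/B)` over the N−m templates common to both
  orders, self-matches excluded, `Inf` sentinel when no (m+1)-matches
  exist. Template distance is Chebyshev (max-norm) for both entropies, with
  tolerance `r = 0.2 · sd(channel)` and `m = 2` (the conventional defaults;
  the chain fixes neither).
* **Permutation entropy** — natural-log Shannon entropy of ordinal patterns
  (order 3, delay 1 by default); ties are ranked by temporal order of
  appearance (stable sort), and a normalized variant (÷ log m!) is off by
  default.
* **Moments** — skewness and excess kurtosis use biased (1/N) moments with
  the population standard deviation, while variance and sd use N−1. The
  mixed convention is deliberate: it reproduces the printed forms of the
  four statistics exactly (for {−1, +1}: skewness 0, excess kurtosis −2,
  variance 2, sd √2).

Undefined features (constant channels, no entropy template matches)
propagate as `NA` sentinels and flag the epoch; flagged epochs are excluded
from training rather than imputed. Normalization is a per-feature z-score
fitted on the training split only, pooled over the dataset (per-subject
normalization is a caller-side choice: the normalizer is an explicit
object). Length dependence of features is addressed by using densities and
per-sample conventions throughout; trials are not truncated or resampled.

The two entropies share one fused C++ pass in `featurize_epoch` (an
exhaustive O(n²) template count is the bottleneck at 62 channels ×
hundreds of epochs); the fused path is tested to equal the individual
implementations to machine precision, and those in turn equal literal R
double-loop oracles.

## Classification

Six classifiers with fixed hyperparameters: random forest (100 trees), KNN
(k = 5), linear SVM, Gaussian naive Bayes, logistic regression with L2
penalty (ridge multinomial fit, λ = 1/n — the conventional unit-cost
regularization), and a depth-10 decision tree. The SVM is trained
one-versus-rest; because majority voting is undefined for OVR, prediction
takes the argmax of the binary decision values, with ties broken by
training-class frequency and then fixed class order — a deterministic,
documented completion. KNN exposes only the winning-class vote share, so
its score matrix spreads the remainder uniformly; the argmax (and therefore
every reported metric) is unaffected.

Splits are stratified (proportions preserved within one sample per class),
disjoint, exhaustive and seed-reproducible; 80/20 is the default protocol.
Metrics are accuracy and macro-averaged precision/recall/F1 with empty
denominators counted as 0, plus the confusion matrix (rows = truth). All
metric code is pinned to an independent tallying oracle on random
prediction sets.

## P300 speller chain

Each intensification yields a 0–667 ms epoch, band-passed with an order-8
Chebyshev type-I filter (0.1–10 Hz). The passband ripple is not fixed by
the chain's description; 0.5 dB is the default and it is configurable. The
expanded 16th-order transfer function of this design is numerically
unstable (poles leave the unit circle under coefficient rounding), so the
filter is designed in zero-pole-gain form and applied as a cascade of
second-order sections, causally (forward-only), matching an online-capable
system. Decimation keeps every k-th sample, `k = floor(fs / (2·f_high))`,
with no extra anti-aliasing stage because the band-pass at 10 Hz already
provides it — hence the precondition that decimation follow the filter.

Phase 1 scores each 896-dim vector for P300-ness (default classifier:
random forest; the full menu is available). Phase 2 sums raw scores per
row/column id over repetitions and intersects the argmax row (ids 7–12) and
column (ids 1–6); ties break toward the lowest id. Score summation rather
than vote counting is used because it is the convention of
reference-standard matrix spellers and uses the full score information.

## Controller

The FSM is a total deterministic function on (state × four commands),
validated at load: every missing pair is reported by name, and MAIN must be
reachable from every state (checked by reverse reachability). Only four
transitions of the application table are fixed by the framework design
(right hand → browser, left hand → OS explorer, both hands → email → inbox);
the rest of the shipped YAML is a marked, overridable completion in which
REST backs out toward MAIN, RIGHT_HAND advances a cyclic highlight and
BOTH_HANDS selects. Actions are labels only — binding them to real
applications (email, browser, OS) is out of scope. States flagged
`text_entry` signal the caller to hand off to the P300 speller; the FSM
itself has no side effects, which keeps it fully testable.

## Synthetic data: what it emulates and what it does not

The MI generator produces 1/f Gaussian background noise (α = 1,
sd 10 µV) on all channels plus 10 Hz (amplitude 10 µV) and 20 Hz (5 µV)
oscillations with random phase over the C3- and C4-centered clusters. ERD
is amplitude attenuation by `erd_depth` on the cluster contralateral to the
imagined hand (both clusters for both-hands, none at rest); `erd_depth < 0`
models synchronization. The defaults put the rhythms at the same order of
magnitude as the background, a realistic regime in which the chain must
actually use the band-power contrast.

The P300 generator schedules, per character, `repetitions` random
permutations of the 12 row/column ids at a 175 ms stimulus-onset asynchrony
(100 ms flash + 75 ms gap), so consecutive post-stimulus windows overlap as
in real sessions. Target intensifications add a positive Gaussian
deflection (5 µV, 300 ms latency, 100 ms FWHM — the FWHM convention is the
package's) on eight centro-parietal channels. Only the deflection's
positivity and ≈300 ms latency are constraints of the paradigm; shape and
topography defaults are literature-style choices.

Neither generator includes eye-blink/EMG artifacts, inter-channel noise
correlation (available as an optional smoothing-mixing flag is deliberately
not the default), non-stationarity, or inter-subject variability.
Consequently, passing end-to-end tests shows that the chains correctly
exploit the generative contrast they are designed for — not that the
specific accuracy numbers transfer to real recordings. Both generators are
pure functions of (config, seed).

## Problem sizes and tolerances used in the tests

The test suite and acceptance script run at desk scale, chosen to keep the
statistical checks well-powered: MI bracketing uses 100 trials/class at ERD
depths 0.8 (expect logistic-regression accuracy > 0.80) and 0 (expect
chance, 0.25 ± 0.1 on 80 held-out trials); speller recovery trains on a
10-character session and requires perfect decoding of a 10-character test
session at default SNR with 15 repetitions, plus strictly higher accuracy
at 15 repetitions than at 1 over a 100-character session; oracle
equivalence for the entropies, moments and metrics is checked at 1e-10 on
signals of length ≤ 50; AR(4) recovery within ±0.05 at n = 10,000. The
85-character bookkeeping run (15,300 vectors of dimension 896) is executed
in full.

## Known limitations

* EDF support is a minimal 16-bit uniform-rate subset (plus the plain-text
  delimited dialect); EDF+ annotations are not parsed — events live in the
  sidecar TSV.
* No CSP/wavelet/Riemannian features, channel selection, sliding-window
  features, or deep models; no hyperparameter search.
* The speller's phase-2 decoder assumes complete coverage of all 12 ids per
  character and errors otherwise; partial sessions must be filtered first.
* Online/streaming acquisition is out of scope; the causal filtering merely
  keeps the chain online-capable.
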