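---
title: "Classifying cat behaviour from triaxial accelerometers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cat behaviour from triaxial accelerometers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felacc)
```

# The problem

Continuous behavioural monitoring of domestic cats by video scoring is
labour-intensive and misses infrequent behaviours. Body-worn triaxial
accelerometers record both static acceleration (the orientation of gravity in
the device frame, i.e. posture) and dynamic acceleration (movement), and
machine-learning classifiers can map short windows of that signal onto an
ethogram of behaviours. `felacc` implements that full analysis path for a
two-device design — one accelerometer on a collar (ventral) and one on a
harness (left shoulder) — sampled at 30 Hz with a ±8 g dynamic range:

1. a seeded synthetic-study generator with known ground truth;
2. ingestion of ActiLife-style raw CSV and BORIS-style annotation exports,
   aligned on 1 s epochs;
3. 32 per-epoch identifier variables;
4. random-forest (RF) and supervised self-organizing-map (SOM) classifiers
   per mounting location;
5. an iterative merge/remove "modelling round" protocol;
6. confusion-matrix metrics (per-class accuracy, precision, sensitivity,
   specificity; overall accuracy; Cohen's kappa);
7. daily activity budgets compared by log-link Dirichlet regression.

# The synthetic study generator

Real annotated cat-accelerometer data cannot ship with a package, so every
stage is exercised against simulated studies whose ground truth is known.
The defaults in `sim_config()` reproduce the target study design: **12 cats,
7 consecutive days, both mounts, 30 Hz**, one annotated 5 h window
(09:00–14:00) on day 1, and roughly 25% of annotated seconds lost to
"out of sight"/"other" codes (matching the share such codes take in the
motivating dataset, 42,511 of 166,754 s).

## Behaviour sequences

Behaviour is a semi-Markov chain: bout durations are gamma distributed
(configurable shape, default 2 — bouts are less variable than exponential,
which matches the intuition that a cat that has settled to sleep stays
settled), rounded up to whole seconds; successors are drawn from a
transition-weight matrix with zero diagonal. The default weights draw each
successor with probability proportional to `occupancy / mean_dwell`, so the
long-run time shares approximate the configured occupancies. Default
occupancies put ~73% of time in inactive postures (lying 44%, sitting 21%,
standing 7.5%), ~16% in maintenance, and a few percent in locomotion, with
rare swift behaviours (jumping, shaking, fighting, playing) at fractions of
a percent — the observation pattern typical of colony-housed cats. Fighting
and playing are configured so rare (≈10 s and ≈3 s per study) that
preprocessing removes them, as happened in the motivating study.

## Acceleration signatures

Each behaviour has a statistical signature, not a biomechanical gait model:
a unit gravity vector in the body frame (cranio-caudal, dorso-ventral,
lateral) describing posture; a sinusoid of amplitude `dyn_amp` (g) and
frequency `gait_freq` (Hz) on the cranio-caudal axis for gait; and isotropic
Gaussian noise. Device axes follow the mounting conventions: collar X/Y/Z =
lateral / dorso-ventral / cranio-caudal; harness X/Y/Z = cranio-caudal /
dorso-ventral / lateral. Trotting/walking and scratching/grooming are given
deliberately similar signatures so the merge protocol sees realistic
confusions; eating has a distinctive forward-pitched gravity direction.

The collar is attached less rigidly than the harness, so collar traces
additionally carry (i) an Ornstein–Uhlenbeck-style angular drift about the
neck axis (stationary sd 0.25 rad, time constant 30 s) modelling collar
rotation, and (ii) a damped 3 Hz ringing (amplitude 0.25 g, time constant
1.5 s) on the lateral axis after every active→inactive transition, modelling
residual device movement after the cat stops. The harness applies neither.
This makes collar features noisier than harness features, which is the
qualitative behaviour attachment-rigidity arguments predict.

What the generator does **not** emulate: realistic gait harmonics and
impacts, transitional postures, inter-cat variability in signatures,
device calibration error, and annotation mistakes. Passing tests therefore
demonstrate that the pipeline machinery is correct and that the protocol
behaves as specified under known ground truth — not that any particular
accuracy level will be attained on real animals.

## Memory and determinism

A full default study is ~435 million triaxial samples (≈10 GB), so
`generate_study()` stores only the ground-truth label sequences and derives
per-(cat, mount, day) seeds; `study_trace()` synthesizes any requested trace
on demand, deterministically. The collar's angular drift restarts from its
stationary distribution at each day boundary (the OU process is stationary,
so this does not change the marginal law). One master seed fans out to all
sub-seeds via 31-bit draws under R's RNG, so every stage is independently
reproducible and all derived seeds stay within integer range.

# Epochs and the 32 identifier variables

Raw samples are cut into non-overlapping 1 s epochs of 30 samples; epoch
`k` covers samples `[30k, 30(k+1))` on the study clock (0-based, half-open;
annotation second *s* maps to the same interval, with an optional
whole-second device/video clock offset). Trailing partial epochs are
dropped. Per epoch, `extract_features()` emits, in a fixed documented
order: mean, sum, min, max, sd, skewness and kurtosis per axis (21);
pairwise Pearson correlations (3); the same seven statistics of the
per-sample vector magnitude `VM = sqrt(X² + Y² + Z²)` (7); and ODBA (1).

Numerical conventions (the source material leaves them open, so they are
fixed here and configurable where noted):

* **sd** is the sample standard deviation (n − 1).
* **Skewness/kurtosis** are population moment ratios (`m3/m2^1.5`,
  `m4/m2²`, kurtosis non-excess). Zero-variance windows would give NaN;
  they are encoded as 0 and flagged in a `degenerate` quality column so
  classifiers never see missing values. Correlations involving a
  zero-variance axis are likewise 0 + flag.
* **ODBA**: each axis is smoothed by a centred 30-sample moving average
  (15 samples before, 14 after, truncated at trace edges); the per-sample
  dynamic residual is the sample minus its smoothed value, and an epoch's
  ODBA is the sum of absolute residuals over the three axes — the standard
  dynamic-body-acceleration construction. A printed-formula variant
  (`dba_mode = "as_printed"`: epoch sums minus summed moving average,
  no absolute value) is available for comparison; the absolute form is the
  default because without the absolute value the statistic is nearly zero
  for any symmetric oscillation and carries almost no information.

# Classifiers

One model is fitted per (technique, mounting location).

**Random forest.** 500 trees, majority vote, `mtry = floor(sqrt(32)) = 5`.
The all-variables reading of the source description (`mtry = 32`, i.e.
bagged trees) is available via `rf_params(mtry = 32)`; the square-root
default is used because it is the long-standing classification default of
the R random-forest implementations. Trees are scale-invariant, so RF sees
the raw features. The backend is `ranger` (single-threaded, seeded, hence
deterministic).

**Supervised SOM.** Written in this package (R driver, C++ inner loop).
Features are z-scored on training statistics (never on test data). Each map
unit carries a fused codebook: a 32-vector feature layer and a one-hot
class layer. The winner for a training sample minimises a weighted sum of
per-layer squared distances, each layer divided by its running mean distance
scale so that a 32-dimensional feature space and a K-dimensional indicator
space are commensurable; the layers are mixed by `class_layer_weight`
(default 0.5). The winner and its neighbours (Gaussian kernel on an 8 × 6
hexagonal grid; radius decays linearly from 2/3 of the map diagonal to 1
across passes) move toward the sample in both layers, with the learning
rate decaying linearly 0.05 → 0.01 over `rlen = 100` passes, each pass
presenting all samples in seeded random order. Prediction maps a new epoch
by the feature layer only and reads the argmax of the winner's class
codebook. Only `rlen = 100` is inherited from the source description; the
grid size, topology, learning rates and neighbourhood mirror the documented
defaults of the standard Kohonen toolkit and are recorded as assumptions.

# The modelling-round protocol

Before round 1, `preprocess_labels()` applies the motivating study's filtering
rules: the non-behaviour codes "out of sight" and "other" are removed;
unobserved behaviours are removed; the two jumping variants merge into
"jumping"; behaviours observed fewer than 11 s are removed (the default 11
reproduces that study's removals of classes with n ≤ 10). Note that
allogrooming — an "other"-category social behaviour in the ethogram — is
*retained*: only the two bookkeeping codes are excluded by category,
which is what leaves its 15 round-1 classes.

Each round then: applies its class mapping; caps every class at 7000
epochs (5000 in round 4) by seeded downsampling, counteracting the extreme
imbalance of lying; splits 70/30 stratified by class (stratification
prevents empty test classes for rare behaviours); trains; and evaluates on
the held-out 30%. Caps of 7000 are re-applied in every round (whether the
original analysis re-capped merged classes in rounds 2–3 is not stated;
re-capping keeps the rounds comparable). The four fixed plans
(`fixed_round_plans()`) reproduce the reference sequence: 15 classes → 8
(six removals; trotting + walking → "active") → 6 (scratching → grooming;
littering dropped, as in the reference round-3 class set) → the 3 ethogram
categories.

`propose_round_plan()` also provides the rule in algorithmic form for
"auto mode": a class with zero true positives or sensitivity below 0.20
(the source never quantifies "low"; 0.20 is configurable) is reassigned by
its largest off-diagonal row cell — merged into that class if both share an
ethogram category, removed otherwise; ties break toward the more frequent
target, making the rule deterministic. Auto mode stops when a proposed plan
changes nothing, when neither overall accuracy nor kappa improves, or when
three classes remain. Merging rewrites labels only; features are never
recomputed.

# Evaluation

From each held-out confusion matrix (rows observed, columns identified):
per-class one-vs-rest TP/TN/FP/FN; accuracy `(TP+TN)/N`; precision
`TP/(TP+FP)`; sensitivity `TP/(TP+FN)`; specificity. The specificity
denominator follows the printed equation `TN/(TN+FN)` by default
(`mode = "as_printed"`) so reported numbers can be reproduced, although
the conventional definition is `TN/(TN+FP)` (`mode = "standard"`); the
printed form is almost certainly a typo, and the difference is documented
prominently rather than silently corrected. Metrics with zero denominators
are `NA` ("undefined") — never 0 — except sensitivity with TP = 0, FN > 0,
which is a true 0. Overall accuracy is the micro-averaged diagonal share
trace(x)/N, and Cohen's kappa uses the count form

κ = (N·Σxᵢᵢ − Σxᵢ₊x₊ᵢ) / (N² − Σxᵢ₊x₊ᵢ),

which is algebraically identical to (p₀ − pₑ)/(1 − pₑ) (property-tested on
random matrices to 1e-12), with the Fleiss bands: > 0.75 excellent,
0.40–0.75 fair to good, < 0.40 poor. No significance test accompanies
kappa (none is specified for it in the source material).

# Activity budgets and Dirichlet regression

Final models predict every epoch of the days not used for training;
per-class frequencies per cat-day are normalised into compositions.
Because some classes can be predicted 0% of the time and the Dirichlet
density is undefined on the boundary, compositions are pulled inside the
simplex by the standard adjustment `y* = (y(n−1) + 1/K)/n` before
likelihood work.

`dirichlet_reg()` implements the common parametrization with log link:
αₖ(x) = exp(xᵀβₖ), one coefficient vector per class. The likelihood is
maximised by BFGS with the analytic gradient
Σᵢ xᵢ αᵢₖ (ψ(αᵢ₀) − ψ(αᵢₖ) + log yᵢₖ), starting from a method-of-moments
fit; standard errors come from the inverse observed information (numerical
Hessian at the optimum), giving per-coefficient Wald z and two-sided p
values, and `compare_budgets()` tests arbitrary design contrasts per class.
Non-convergence is flagged on the returned object, not thrown. Day enters
as a categorical covariate; p values across behaviours are reported raw
(no multiplicity correction), matching the reporting style of the
motivating analysis. The mean/precision parametrization is out of scope.

# Problem sizes and numerical checks

The package's own test suite runs the full protocol once on the default
study (12 cats × 18,000 annotated seconds × 2 mounts ≈ 432,000 labelled
epochs; ~34,000 training rows in round 1 after capping) — 16 models in
roughly ten minutes on one core — plus module tests at small scale.
Simulation-based checks use 10⁵-second label sequences for stationarity,
10-seed separable-cluster oracles for both classifiers, finite-difference
validation of the Dirichlet score, 1000-replicate Wald type-I calibration,
and brute-force oracles for ODBA and kappa. `scripts/acceptance.R`
regenerates the default study from a command-line seed and recomputes the
minimum held-out overall accuracy across all 16 models.

# Known limitations

* Signatures are statistical stand-ins; absolute accuracy values on
  synthetic data say nothing quantitative about real cats.
* The SOM grid/neighbourhood settings of the original analysis are
  unrecoverable; different settings change SOM (not RF) results.
* The motivating study's per-behaviour observation counts exist only for some
  classes; synthetic occupancies for the rest are design choices.
* A reported total of 124,230 retained datapoints differs by 2 from the
  arithmetic of its reported removals (124,232); the package does not
  force either number.
* Only CSV dialects are read; vendor binary formats are not.
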