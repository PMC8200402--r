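---
title: "Methods: automated grading of neonatal EEG background activity"
author: "neobg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated grading of neonatal EEG background activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Continuous EEG monitoring in the neonatal intensive care unit tracks the
*background activity* — the ongoing spontaneous cortical activity whose
grade reflects brain state and recovery after insults such as birth
asphyxia. Clinicians grade the background on an ordinal scale per
5-minute epoch. `neobg` implements an automated version of that grading:
preprocessing of multi-channel EEG, a bank of 98 quantitative features,
classifier designs trained on multi-rater annotations under
leave-one-subject-out (LOSO) cross-validation, genetic-algorithm feature
selection, agreement statistics, and two bedside displays. A synthetic
EEG generator realizing the clinical score definitions makes the whole
chain testable without patient data.

# The scoring model

The 7-score scheme mixes two dimensions. Discontinuity grades are defined
by the voltage and duration of interburst intervals (IBI): score 1
(tracé alternant, IBI voltage ≥ 25 µV, IBI duration ≤ 6 s), score 2
(same voltage, duration > 6 s), score 3 (tracé discontinu, IBI voltage
< 25 µV) and score 5 (burst suppression, IBI voltage < 5 µV). Amplitude
grades are defined by the continuous envelope: score 0 (continuous),
score 4 (depressed, 5–15 µV), score 6 (very low voltage, < 5 µV). These
inequalities are enforced by the validity method of
`BackgroundClassParams`, so a parameter set inconsistent with its score
cannot be constructed. Scores 0–2 share one clinical interpretation and
are merged into a 5-score scheme by `merge7to5()` (`{0,1,2}→0, 3→1,
4→2, 5→3, 6→4`). REJECT (ungradable) epochs are stored as `NA` and are
excluded from every statistic.

# The synthetic generator

`simulateEpoch()` realizes one class: all channels share one burst gate
or slow amplitude envelope (the background is a global brain state),
with independent 1/f^α carrier noise per channel (α = 1.2, band-limited
0.5–30 Hz). Burst and IBI durations are gamma-distributed (shape 6)
around the configured means, and gates have 0.25 s raised-cosine edges,
yielding burst-suppression morphology with controllable IBI statistics.

Two numerical choices matter. First, the carrier is *amplitude
stabilized*: colored noise is divided by its own smoothed analytic
envelope and clipped at ±1.2, so that multiplying by half the target
envelope realizes the requested local peak-to-peak voltage (tested to
10%) while never exceeding 1.2× it — this keeps the strict class bounds
(e.g. < 5 µV for very low voltage) valid sample-by-sample. Second, the
continuous class 0 has no quantitative clinical definition; the default
25–50 µV envelope is a convention and remains configurable.

`simulateRecording()` concatenates class segments along a trajectory
with 20 s raised-cosine crossfades (overlap-added so the total duration
is exact); the ground-truth label of each 5-min epoch is the class
occupying most of it. `injectArtifacts()` adds the two artifact kinds
the preprocessing scan targets: ±500 µV-exceeding transients and
constant-valued (flat) runs ≥ 1 s. `simulateRaters()` produces expert
annotations as noisy copies of the truth with neighbouring-score
confusions.

What the generator does *not* emulate: sleep graphoelements and spindle
activity, seizures, electrode-impedance drift, and realistic artifact
morphology beyond the two kinds above. Passing label-recovery tests on
this data therefore demonstrate that the pipeline recovers classes that
are separable by the clinical definitions — not clinical-grade accuracy
on real recordings.

# Preprocessing

The chain runs in fixed order: per-sample artifact scan (|x| strictly
greater than 500 µV, or a flat run ≥ 1 s; NaN masked with a warning) on
the native-rate signal, zero-phase 5th-order Chebyshev type-II band-pass
(0.5–35 Hz passband; stopband edges 0.25/40 Hz at 40 dB — tests assert
the realized response, not the nominal edges), resampling to 64 Hz
(6th-order Butterworth anti-aliasing at 28 Hz, then cubic-spline
evaluation on the exact 64 Hz grid), segmentation into non-overlapping
5-minute epochs of exactly 19,200 samples (trailing remainder dropped),
and rejection: a channel is rejected in an epoch when ≥ 25% of its
samples are masked, an epoch when ≥ 50% of channels are rejected. Both
thresholds are arguments, because the feature-evaluation sweep re-runs
rejection at {0, 10, 25, 50}%. The artifact mask is computed before
filtering (filtering blurs true amplitudes) and carried to 64 Hz by
nearest-sample mapping. Retained channels keep all their samples — whole
channels, not segments, are rejected.

A numerical caveat: the 10th-order band-pass recursion with a 0.25 Hz
edge is ill-conditioned, so floating-point linearity of the filter chain
holds to about 1e-4 relative, not machine precision; the test suite
checks linearity at that tolerance.

# The feature bank

`featureRegistry()` declares exactly 98 features over six categories —
amplitude (22), spectral (21), complexity (11), discontinuity (26),
modulation (11) and synchrony (7) — each with a documented
parameterization. The five features reported as most selection-robust
are implemented exactly: the mean and SD of the amplitude modulation
(analytic-signal envelope, 1 Hz low-pass), the activation synchrony
index, the average slope of the multiscale entropy curve, and 9–11 Hz
band power. The remainder fill the categories with the standard neonatal
qEEG canon (range-EEG percentiles, Hjorth parameters, line length,
zero crossings, sub-band absolute/relative powers, spectral edge
frequencies and entropy, sample/approximate/permutation entropy,
Lempel–Ziv and fractal complexity, suppression ratios and burst/IBI
statistics at the clinical 5/25 µV thresholds, envelope statistics, and
interhemispheric synchrony measures). The original full list lives in
unavailable supplementary material, so this registry is this package's
own versioned, testable realization of the stated categories.

Conventions worth noting:

* Spectral features use a Welch periodogram, 8 s Hann segments, 50%
  overlap (0.125 Hz resolution resolves the 2 Hz-wide 9–11 Hz band),
  scaled so band powers integrate to variance (a 10 µV, 10 Hz sine gives
  ≈ 50 µV² in 9–11 Hz).
* The activation synchrony index binarizes each channel's envelope at
  its own 75th percentile and takes the phi correlation of the binary
  activation trains: symmetric, 1 for identical channels, ≈ 0 for
  independent burst timing, and defined as 0 for degenerate (constant
  envelope) inputs. The original formulation lives in an external
  reference; this parameterization is recorded here per registry entry.
* Entropy measures use m = 2, r = 0.15·SD (fixed across scales), scales
  1..20, computed on the central 1,024 samples (16 s) of each epoch;
  approximate entropy uses 512 samples. These window sizes keep the
  O(n²) template matching tractable at cohort scale and are stated in
  the registry.
* Features are computed per channel and summarised across non-rejected
  channels by the median. Synchrony features are computed per homologous
  electrode pair (F3–F4 and so on; all pairs when no homologous pair
  exists) and summarised by the median over pairs with both members
  retained. In the per-channel array they are undefined, so
  channel-restricted classification imputes them from training-fold
  medians.
* The per-channel values and masked fractions are retained in the
  feature table's metadata, so `aggregateFeatures()` can redo the
  channel-median at any rejection threshold without recomputing a single
  feature — this is what makes the artifact-threshold sweep cheap.

# Labels and training sets

Annotation smoothing uses a centered running median over non-REJECT
neighbours (default window 5 epochs = 25 min; classifier outputs use
window 7), shrunken at the series edges, with the lower-middle value on
even counts so the output remains a valid ordinal score; REJECT
positions are never overwritten. The pipeline order is fixed as merge →
smooth. Two-rater training sets come in two modes: CONS keeps agreeing
epochs once; ALL emits one row per rater per epoch, so consensus epochs
carry exactly twice the weight (implemented by duplication). SMOTE
(k = 10, capped at class size − 1) oversamples minorities to the
majority count with uniform convex combinations of nearest-neighbour
pairs. Hierarchical grouping defaults: severity = normal {0,1,2} /
moderate {3,4} / severe {5,6}; continuity = continuity-defined
{0,1,2,3,5} vs amplitude-defined {4,6}; both are arguments because the
original group assignments are not published in detail.

# Classifier designs

All designs normalize features to z-scores with training-fold statistics
only (population SD; constant features are centered with a warning) and
impute missing values by training-fold medians.

**SVM.** One-vs-one error-correcting ensemble of K(K−1)/2 binary linear
SVMs (`e1071::svm` as the binary learner). Each learner's decision
values are calibrated to pair-conditional probabilities by a sigmoid fit
with regularized targets (finite even under perfect separation), and
multiclass posteriors are the normalized average of the pairwise
probabilities, which sums to 1 exactly. The box constraint can be tuned
by a 1-D Bayesian optimization (squared-exponential GP, expected
improvement) of the internal subject-grouped 5-fold CV accuracy over
log-uniform 1e-3..1e3; the tuning objective evaluates the same binary
learners through `e1071`'s compiled one-vs-one voting for speed.

**MFNN.** Two tanh hidden layers (default 30, 15) and a tanh output
layer; class probabilities are the softmax of the output activations.
Training is full-batch gradient descent on squared error against ±1
targets, momentum 0.8, initial learning rate 0.1 reduced by 75% after
every 6,000 iterations (a repeating schedule, exposed as
`mfnnLearningRate()`), stopping at 120,000 iterations, training RMSE
< 1e-3, or when the inner 10%-holdout validation loss stops improving.

**RNN.** The second hidden layer feeds back into itself with a one-epoch
delay. Forward weights start from the trained MFNN; recurrent weights
start small-random. Real-time recurrent learning tracks the exact
sensitivities of the recurrent layer's state to its own parameters
(recurrent matrix, second-layer weights and bias); the input and output
layers are fine-tuned with instantaneous per-step gradients. Extending
the exact RTRL recursion to the input layer would multiply the per-step
cost by the input dimensionality for no measurable benefit at this model
scale, so the recursion is scoped to the recurrent layer. Learning rates
are very small and per-class, scaled inversely to class frequency; the
hidden state resets at subject boundaries, so subject order is
immaterial. With zero recurrent weights and no training the RNN
reproduces its source MFNN exactly (a tested identity).

**LOSO.** One fold per subject; imputation, z-scoring, SMOTE,
hyperparameter search and ALL-mode rater duplication all happen inside
each training fold. Per-fold seeds derive deterministically from the
master seed. Hierarchical approaches compose P(score) = P(group) ×
P(score | group), which preserves unit row sums; recurrent designs are
flat-only since hierarchical grouping breaks the epoch sequence.

# Feature selection

The GA searches feature bitmasks with fitness = inner subject-grouped
5-fold CV accuracy of the linear-SVM wrapper on the masked features
(full LOSO inside the GA would be cost-prohibitive). Reference settings:
population 100, two-point crossover at rate 0.6, per-gene bit-flip
mutation at rate 0.1, 50 generations, at most 5,000 distinct fitness
evaluations (memoized). Parent selection is fitness-proportional
roulette. Because a mutation rate of 0.1 per gene rewrites ~10 of 98
genes in every child, the single elite slot carries the *best chromosome
found so far* rather than the current generation's best; without this
the incumbent solution is destroyed almost every generation and the
search cannot converge at the stated budget. All-zero chromosomes are
repaired to a random single feature. `thresholdSweep()` re-runs
rejection and the GA at artifact thresholds {0, 10, 25, 50}% and reports
the features selected in over half of the final population at every
threshold; `accuracyVsCountCurve()` reports LOSO accuracy as features
are added in selection-rank order.

# Performance measures

Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with chance agreement from the marginals;
when pₑ = 1 (both raters constant) κ is defined as 1 for perfect
agreement, otherwise 0. Macro averages are unweighted class means (a
class with no support contributes 0, with a warning); weighted averages
are support-weighted. Bootstrap confidence intervals resample epochs
(prediction/reference pairs) with replacement, n = 1,000, percentile
2.5/97.5 bounds; subject-level resampling is a caller-side option by
restricting the inputs. REJECT pairs are excluded symmetrically
everywhere. `compositeAgreement()` reports the pairwise κ among two
raters and a classifier with a non-inferiority flag (the classifier's
worse agreement with either rater is at least the inter-rater κ).

# Visualization

The heatmap maps per-epoch score probabilities through a monotone
"hot"-style ramp (black → red → yellow → white), scores ordered by
severity, with optional per-epoch renormalization (raw posteriors
already sum to 1; the flag exists because both display conventions are
in clinical use) and a neutral grey for REJECT epochs. The Background
Trend is the probability-weighted mean score, smoothed by a 3-epoch
moving average (shrunk at the edges); its uncertainty band is the
probability-weighted SD of the class values around the unsmoothed trend
— zero exactly for one-hot posteriors, √2 for a uniform posterior over
values 0..4. The band definition is this package's recorded choice; an
inter-quantile band of the discrete distribution would be a drop-in
alternative. Class values default to the linear severity order {0..4} on
the 5-score scale, kept linear despite the known two-dimensional tension
around the depressed/low-voltage grades. `renderReport()` draws both
panels with optional expert overlays; the computed matrices and trend
are deterministic for fixed input (the PDF container itself embeds a
creation timestamp, as R graphics devices do).

# Scaled experiments in the test suite

The package's tests exercise the whole chain on synthetic data at sizes
chosen to finish on one CPU in minutes:

* Label recovery: 10 subjects × 3 h (4-channel reduced montage F3, F4,
  P3, P4 at 200 Hz), trajectories as random walks over one
  representative of each merged class with blocks of 35–60 min (the
  final block absorbs any remainder so every state lasts ≥ 35 min), two
  synthetic raters at 90% per-epoch agreement, flat SVM on ALL-mode
  annotations, 5-score scheme, smoothing of annotations (window 5) and
  outputs (window 7). Expected LOSO accuracy ≥ 0.90 against the ground
  truth, with smoothing not reducing it.
* GA recovery: a planted dataset with 6 classes where informative
  feature j marks class j (mean shift 3, unit noise) among 93 pure-noise
  features, 240 rows over 10 subjects — each informative feature is
  individually necessary, so full recovery is a meaningful target.
  Reduced GA budget: population 30, 15 generations; all 5 informative
  features are expected in the best subset in ≥ 8 of 10 seeded runs.
* Oracle equivalence: κ, confusion metrics, running medians,
  channel-median aggregation, Welch band power and sample entropy are
  checked against independent brute-force reimplementations on 100+
  random small instances.

# Known limitations

* The feature registry is a faithful realization of the stated
  categories, not a numeric clone of the original closed-source Matlab
  bank; absolute feature values are not comparable across
  implementations.
* The synthetic generator's class separability is by construction close
  to the clinical definitions; real neonatal EEG is far more ambiguous,
  so recovery accuracies here bound the pipeline's correctness, not its
  clinical performance.
* RTRL is exact only for the recurrent layer's parameters (see above).
* The EDF writer/reader covers plain 16-bit EDF with equal per-channel
  rates — sufficient for round-tripping this package's recordings, not a
  general EDF+ implementation.
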