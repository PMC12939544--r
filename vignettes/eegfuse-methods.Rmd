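---
title: "Methods: multi-domain EEG feature fusion for depression vs. negative emotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-domain EEG feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transient negative emotion (sadness, fear, disgust in a healthy brain) and
pathological depression share surface symptoms but differ in their
electrophysiology. `eegfuse` implements a complete pipeline for telling the
two apart from short 8-channel EEG segments, using three complementary
feature families extracted per channel:

* **F1, spectral**: the ratio of alpha-band (8–13 Hz) to beta-band
  (14–30 Hz) power. Beta activity tracks arousal and anxious tension, alpha
  tracks cortical inhibition; their ratio is a scale-free marker of
  emotional state that cancels inter-subject amplitude differences.
* **F2, spatial**: normalized hemispheric alpha asymmetry. Under the
  approach–withdrawal hypothesis, depression shows relative left-frontal
  hypoactivation (elevated left alpha); for each electrode `ch` with mirror
  `m(ch)` we compute `A(ch) = (P_a(ch) − P_a(m)) / (P_a(ch) + P_a(m))`,
  bounded in [−1, 1].
* **F3, non-linear**: sample entropy (m = 2, r = 0.2·SD), a template-match
  complexity measure. Depressed EEG is more regular ("loss of complexity"),
  so entropy is lower.

Epochs are 7.5 s at 128 Hz (960 samples) over the canonical montage
Fp1, Fp2, F3, F4, F7, F8, C3, C4 — prefrontal/frontal/central electrodes
chosen for their role in emotion regulation; odd indices are left
hemisphere. Each epoch yields a 24-dimensional feature vector
(8 ratios ∥ 8 asymmetries ∥ 8 entropies), and a balanced cohort of 510
epochs per class yields the 1020 × 24 matrix the classifier consumes.

## Feature extraction choices

**Wavelet packet decomposition.** Band signals are isolated with a
four-level WPD (db4 by default; any of the shipped orthonormal Daubechies
filters may be substituted, non-orthogonal wavelets are refused because the
leaf-energy invariant would fail). Leaves are returned in frequency
(sequency) order, each nominally covering 4 Hz at the analysis rate; the
natural filter-bank order is mapped to frequency order by the Gray-code
permutation. Periodic boundaries plus orthonormality give exact energy
conservation and perfect reconstruction (both are asserted to 1e−6
relative in the tests).

**Band power.** The leaves overlapping a band are reconstructed to a time
signal, its Welch PSD (1 s Hann windows, 50% overlap — fixed in the
parameter sidecar for reproducibility) is integrated over the exact band.
Reconstruct-then-integrate resolves the mismatch between band edges
(alpha ends at 13 Hz) and the 4 Hz leaf grid without redefining the bands.
One *guard leaf* is kept on each side of the overlapping set: the short
db4 filters have wide transition bands that park roughly a fifth of a
mid-band tone's energy in the adjacent leaves, and without the guard a
unit 10 Hz sine recovers only ~0.34 of its 0.5 mean-square power instead
of ~0.45. The Welch integral still runs over the exact band, so content
genuinely outside it is not counted. Band power (not mean density) is
used in the ratio; the two differ by a constant bandwidth factor, recorded
in the sidecar.

**Asymmetry.** The normalized (L−R)/(L+R) form is computed per channel
against its mirror, not per pair, so the feature vector carries 8
asymmetries with the built-in redundancy `A(left) = −A(right)`; this keeps
24 = 3 × 8 columns and lets importance rankings name individual
electrodes.

**Sample entropy.** `SampEn = −ln(A/B)` with Chebyshev distance,
self-matches excluded, both template lengths drawn from the same `N − m`
starting positions. `r` scales with the series SD, making the feature
invariant to affine rescaling; series lengths are restricted to
[100, 5000] where the estimator is stable. A constant series returns 0
(no variability ⇒ no complexity); if no (m+1)-template pair matches, the
maximum estimable value `−ln(1/((N−m)(N−m−1)))` is returned instead of
infinity so the feature matrix stays finite. Both degenerate paths warn,
and rows with non-finite features are rejected outright, never imputed.
The counting loop is compiled (Rcpp); the test suite holds it to *exact*
count agreement with a pure-R brute-force double loop.

## The synthetic generator

Real recordings (stimulus-locked trials with affect ratings, and clinical
resting-state EEG) are optional inputs; every stage is testable without
them through a seeded generator whose epochs carry exactly the three
signatures the features detect:

* each channel is a sum of band-limited oscillators (8 random-phase
  sinusoids per active band, frequencies drawn uniformly inside the band
  with a guard margin of up to 2 Hz — a Hann-windowed tone spreads over
  roughly ±2 of its 1 Hz bins, and the margin keeps ≥95% of Welch power
  inside the nominal band);
* an AR(1) background whose lag-1 coefficient (`regularity`) is the one
  knob controlling sample entropy without touching band structure;
* alpha amplitude scaled by `1 ± asymmetry_coeff` on left/right channels.

The shipped class presets are: depression — theta 0.8, alpha 2.0,
beta 2.0, gamma 0.5, asymmetry +0.15, regularity 0.8; negative emotion —
alpha 3.0 (a 1.5× alpha/beta amplitude contrast, i.e. the negative-emotion
class has the *higher* ratio), asymmetry −0.05, regularity 0.2; background
SD 1.5 for both. Directions follow the empirical findings the features
rest on; magnitudes are package choices, fixed once so that all three
families separate the classes (Mann–Whitney p < 0.05 on ≥7/8 channels at
100 epochs/class) while remaining in a physiologically plausible range.
There is a documented tension in the source literature between
"depression shows elevated alpha and suppressed beta" and the empirical
observation that the negative-emotion cohort had the higher alpha/beta
ratio; the presets follow the empirical direction. A `"null"` preset (the
class midpoint) generates signal-free cohorts for chance-level controls.

What the generator does **not** emulate: ocular/EMG artifacts, electrode
drift, volume conduction, inter-subject variability, or the empirical
distributions of any real dataset. Passing tests therefore demonstrate
that the pipeline recovers the class structure it is designed to detect
when that structure is present — not that real clinical performance would
match.

Rated synthetic trials (63 s: 3 s pre-stimulus baseline + 60 s stimulus,
8064 samples) carry valence/arousal scores on the 1–9 scale; the selection
pipeline keeps trials with valence < 2.5 and arousal < 5 (strict), crops
the steady-state 15–60 s window measured from stimulus onset (the
baseline is skipped explicitly, matching the documented trial layout),
and segments into six non-overlapping 7.5 s epochs per trial. Overlap is
a config option defaulting to 0. The 4–45 Hz band-pass is an order-4
Butterworth applied forward–backward (zero phase); a separate mains notch
is unnecessary after this band-pass and is omitted. No per-epoch amplitude
normalization is applied before feature extraction — F1/F2 are scale-free
ratios and F3's tolerance scales with the SD, so none is needed.

## The classifier

The 24-vector is fused by **multi-head additive attention**: each head
computes `alpha_h = softmax(W_h x + b_h)` and reweights the input
element-wise, `o_h = alpha_h ⊙ x`; head outputs are concatenated and fed
to a dense layer (16 units, ReLU), dropout 0.4, and a sigmoid output.
Training uses Adam (lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e−8 — library-default
moments pinned in the config), batch size 30, binary cross-entropy, a
fixed 30 epochs, no early stopping. Features are z-scored with
training-split statistics stored on the model; this normalization is an
addition beyond the reference description, on by default and switchable
off. The forward and backward passes are written out explicitly in R (the
model has only ~3k parameters, most of them attention weights), which
makes the analytic-vs-finite-difference gradient check part of the
package's contract rather than an article of faith.

The architecture description admits two readings: heads over three
8-dimensional family subspaces (fusion width 24), or heads over the full
24-vector (fusion width 72). Only the full-vector reading yields a
72-dimensional fusion and an attention parameter count of exactly
3·(24·24+24) = 1800 ("~1.8 k"), so `head_input_mode = "full_vector"` is
the default; the subspace reading ships as an option for comparison.
Ablations: `"single_head"` (one head over the full vector, fusion width
24) and `"none"` (features pass straight to the dense layer). The positive
class is depression (label 1); headline precision/recall/F1 are the
depression-class values, and per-class plus macro values are always
emitted.

Cross-validation is stratified 5-fold (plain "5-fold" is underspecified;
stratification preserves the 1:1 ratio in every fold), with per-fold
z-scoring fitted on the training split only — asserted, not assumed, by
the leakage tests.

## Baselines and statistics

The RBF SVM uses nested cross-validation: an outer 5-fold loop for
generalization, an inner 3-fold grid search over C ∈ {0.1, 1, 10, 100}
and γ ∈ {0.001, 0.01, 0.1, 1} (the grids are package defaults; only the
search itself is prescribed). A hard index audit asserts the inner folds
never touch the outer test fold. XGBoost runs the binary logistic
objective with pinned defaults (depth 3, 200 rounds, learning rate 0.1).
The recurrent baseline reshapes the 24-vector into 8 channel-steps of 3
features (the channel axis is the sequence, since the question it probes
is whether the spatial channel arrangement carries sequential structure;
the 3-domain-step alternative is a config option) through a tanh RNN cell
of width 16. All models consume the identical fold object, so out-of-fold
scores are paired — a requirement of the DeLong comparison of correlated
ROC curves, which is implemented from the structural-component covariance
and cross-checked in the tests against an independent reference
implementation.

Screening uses the Mann–Whitney U test (exact enumeration for combined
n ≤ 12 without ties, otherwise the tie- and continuity-corrected normal
approximation) and the Welch t-test, at α = 0.05 with no multiple-testing
correction by default (matching the raw per-channel screening convention;
Benjamini–Hochberg is available but off). Screening is diagnostic:
non-significant channels are reported, never dropped. Feature importance
is permutation importance (accuracy drop over 20 seeded permutations,
min-max normalized so the top feature scores 1.0) because it applies
uniformly to every model; attention-weight summaries are available
separately and are never blended into the ranking.

## Numerical and degenerate-input conventions

* WPD requires length divisible by 2^level; 960 = 60·16 satisfies it.
* Zero beta power (possible only for synthetic input) clamps the ratio to
  a configurable cap with a warning; zero alpha on both mirror channels
  defines the asymmetry as 0 with a warning.
* ROC ties: equal scores collapse to one threshold step, consistent with
  the mid-rank AUC; trapezoidal, rank-based, and DeLong AUCs agree to
  1e−10.
* Both-constant-equal t-test inputs return t = 0, p = 1.
* Every random draw flows through a single integer-hash seed derivation,
  so any result is bit-reproducible from one seed on one thread.

## Problem sizes

The test suite exercises the full-size study conditions where they matter:
the 510-per-class cohort (1020 × 24 matrix, 204-sample test folds), a
zero-gap cohort of the same size for the chance-level control, and a
100-per-class cohort for screening and baseline properties. Statistical
calibration uses 1000 null simulations for the two-sample tests and 500
for the DeLong z. The acceptance script reruns the whole pipeline —
cohort, features, screening, 5-fold attention network, ablations, all
three baselines, DeLong, and the zero-gap control — from a single seed.

## Known limitations

* On the default synthetic conditions the classification task saturates:
  the attention network and every baseline reach ~100% accuracy, so the
  benefit of multi-head attention over its ablations (clearly visible on
  real, noisier data) has no room to express itself here — the ablation
  comparison on this cohort is a contract check, not a performance study.
  For the same reason the real-data performance gap between the SVM and
  XGBoost does not reproduce on the synthetic cohort.
* Artifact removal (ICA) is out of scope; the pipeline assumes pre-cleaned
  signals, as the acquisition side performed artifact rejection upstream.
* The EDF writer/reader covers plain 16-bit EDF with a single data record
  — sufficient for cohort round-trips, not a general-purpose EDF+ tool.
* Whether a published per-class sample count refers to trials or to the
  six epochs each trial yields is ambiguous; the trial-selection helper
  reports both counts (`n_trials_kept` attribute and epoch count).
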