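---
title: "Estimating mind-wandering intensity from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mind-wandering intensity from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mweeg)
```

## The problem

During a sustained-attention task, a subject's attention drifts between the
task and task-unrelated thought (mind-wandering, MW). Thought probes
interrupting the task every few tens of seconds let the subject rate MW
intensity on a 7-point Likert scale, but probes are sparse and themselves
disruptive. `mweeg` implements a regression pipeline that predicts the
per-section MW rating from scalp EEG spectral features, so that MW intensity
can be read out continuously, including in settings where probing is
impossible.

The pipeline is:

1. **Preprocessing** — 0.3–70 Hz band-pass and 50 Hz notch filtering, 1-s
   epoching aligned to task sections, artifact rejection by amplitude and
   gradient thresholds.
2. **Features** — per epoch, band power per electrode in eight frequency
   bands (delta 1.5–6, theta 6.5–8, alpha1 8.5–10, alpha2 10.5–12, beta1
   12.5–18, beta2 18.5–21, beta3 21.5–30, gamma 35–44 Hz), and per section,
   magnitude-squared coherence for every electrode pair in the same bands;
   for a 17-electrode montage this gives (17 + 136) × 8 = 1,224 predictors
   per section. Features and the MW rating are standardized within each
   subject.
3. **Dataset assembly** — subjects whose raw answers span fewer than 2
   Likert points are excluded; whole subjects are split ~2:1 into training
   and test partitions; sections with any |z| > 5 feature are dropped; both
   partitions are scaled by training statistics only.
4. **Predictor selection** — a correlation filter: the absolute Pearson
   correlation |r| of every training feature with the training response,
   swept over thresholds 0, 0.01, … up to the maximum |r|; each threshold
   defines a nested predictor set, plus one extra set holding only the
   single best predictor.
5. **Models** — ε-insensitive support vector regression
   (ε-SVR) with linear and radial-basis (RBF) kernels, hyperparameters
   chosen per predictor set by grid search under k-fold cross-validated
   mean squared error. Five models are reported: RBF and linear at the
   overall best-CV set (Models 1 and 3), RBF and linear at the best-CV set
   among sets using at most 9 electrodes (Models 2 and 4, the
   "portable-device" variants), and ordinary least squares on the single
   best predictor (Model 5).
6. **Evaluation** — held-out Pearson r per model with its correlation
   test, pairwise r-difference tests between models, and a behavioral
   validation correlating per-section reaction-time variance with the MW
   rating within each subject (Fisher-z transform, one-sample Wilcoxon
   signed-rank test).

## The estimator

ε-SVR minimizes

$$ H(\beta) = C \sum_{i=1}^N V_\epsilon\!\left(y_i - f(x_i)\right)
   + \tfrac{1}{2}\lVert\beta\rVert^2, \qquad
   V_\epsilon(r) = \max(|r| - \epsilon, 0), $$

with \(f(x) = \langle \beta, \phi(x)\rangle + \beta_0\) and kernel
\(k(x, z) = x^\top z\) (linear) or
\(k(x, z) = \exp(-\gamma\lVert x - z\rVert^2)\) (RBF). `svr_fit()` solves
the convex dual on a package-computed kernel matrix with the SMO solver of
**kernlab**; for small problems (≤ 64 samples) the solution is then
polished by an exact pairwise coordinate-descent pass on the dual and the
intercept is re-optimized exactly by minimizing the piecewise-linear loss
in one dimension. The test suite verifies the fitted objective against an
independent dense dual-QP oracle to 10⁻⁶ on random small instances.

Hyperparameter grids default to powers of two, C ∈ 2^(−4…2) and
ε ∈ 2^(−6…1); the RBF width is fixed at γ = 1/p (one over the number of
features in the set) rather than searched. Grid-search ties go to the first
candidate in enumeration order; cross-validation folds are a random
row-level partition of the training rows, as equal in size as possible,
under a caller-supplied seed.

## Statistical comparisons

Model accuracies are compared on the same held-out rows, so the default
r-difference test is Steiger's Z for dependent correlations sharing one
variable, using the correlation between the two models' prediction series;
the independent Fisher-z difference is available as an option. P values are
one-sided for the directional hypothesis "model A predicts better" by
default. When two compared models are identical (their prediction series
correlate at 1) the statistic is defined as 0. A correlation of exactly ±1
cannot be tested by the t transform; its p value is reported as the
double-precision floor with a flag. Constant prediction series (possible
when ε exceeds the response spread) are assigned r = 0 with a warning,
since a constant has no linear association.

## The synthetic cohort generator

No public recordings accompany this design, so `sim_config()` /
`generate_session()` synthesize whole cohorts with a known ground truth.
Per subject, a latent MW trace follows a stationary AR(1) process over
sections (coefficient 0.6, innovation SD 0.8, hence stationary SD 1);
probe answers are the per-subject standardized trace plus Gaussian noise
(SD 0.3), affine-mapped and rounded into 1…7. Background EEG is white
noise at 10 µV SD per channel, scaled per subject by a lognormal factor
(log-SD 0.2) so that within-subject normalization matters.

Effects are planted along four pathways, each seeing the latent trace
through its own section-level Gaussian jitter (SD 0.4) — the neural state
driving a feature is a noisy version of the state the subject reports, so
no single feature is a clean readout and combining features genuinely
helps:

* **Primary coherence pathway** — the beta3 content of Pz and O1 is a
  constant-power mixture of private and shared band-limited sources with
  mixing weight `effect_linear * plogis(mw)`; coherence rises monotonically
  with MW while in-band power stays flat, so the effect lives in
  `coh_Pz_O1_beta3` alone.
* **Secondary linear markers** — midline theta power (Fz, Pz) rising with
  MW, posterior alpha1 power (P5, P6, O2, Oz) falling with MW, and two
  fronto-parietal theta coherences (F3–P9, F4–P10) rising with MW, all
  scaled by `effect_secondary`.
* **Non-linear pathway** — beta1 sources on the lateral-prefrontal
  channels F3 and F4 whose in-band power follows the U-shaped link
  `effect_nonlinear * (mw - vertex)^2` with vertex −1. Placing the vertex
  one SD below the mean keeps a monotone component (so the feature passes
  the |r| filter) while leaving substantial curvature that only a
  non-linear model can exploit.
* **Behavioral pathway** — per-trial reaction times are lognormal with
  log-scale SD `rt_base_sd + rt_effect * plogis(mw)`, so RT variance grows
  with MW.

Artifacts are injected as 120 ms, 400 µV half-sine transients into randomly
selected 1-s windows (rate 0.05 by default); they exceed the rejection
thresholds (200 µV peak-to-peak, 150 µV/sample gradient — common EEG
practice, above the generator's background spread) by a factor of two, and
the contaminated windows are recorded in the ground truth so tests can
verify that rejection catches them.

Default effect gains were fixed once, at values that make the planted
correlations clearly recoverable at the pilot cohort sizes used throughout
the test suite (planted |r| ≈ 0.45–0.7). They are stronger than what small
real-data studies report for single EEG features; with cohorts several
times larger the same orderings emerge at weaker gains, but the tests
would then need far more computation per seed.

### What the generator does not emulate

Real EEG has 1/f background spectra, volume conduction (which induces
broad spurious coherence), non-stationary artifacts (drifts, EMG bursts),
and subject-specific spectral peaks. None of these are modeled: passing
recovery tests shows the pipeline's statistical machinery is sound, not
that it will reach any particular accuracy on real recordings.

## Numerical and design choices

* **Spectral estimator**: plain rectangular-window DFT of each 1-s epoch
  (1 Hz resolution), unnormalized, so Parseval reads
  Σ|X_k|² = N Σx². Any fixed normalization cancels in the
  within-subject z-scoring. A Hann taper is available but off by default.
* **Band-to-bin mapping**: a bin belongs to the band whose half-hertz
  interval contains its center; gap bins (12–12.5, 30–35 Hz, …) belong to
  no band.
* **Coherence** is estimated per section across its clean epochs (≥ 2
  required; a single-segment estimate is identically 1) and averaged over
  each band's bins.
* **Filtering** applies the Butterworth cascade (high-pass order 2 at
  0.3 Hz, low-pass order 4 at 70 Hz, band-stop order 2 at 48–52 Hz) as a
  zero-phase frequency-domain multiplication by the two-pass magnitude
  |H(f)|² — the steady-state equivalent of forward-backward filtering
  without its long edge transients.
* **SD convention**: population SD (divide by n) for all normalization
  steps.
* **Split sizing**: round-half-up of n_subjects × test_fraction, at least
  one subject on each side; subject assignment is uniform at random under
  a seed.
* **Screen membership** is inclusive (|r| ≥ threshold), so the top feature
  survives into the top set; the grid stops at the largest step multiple
  ≤ max |r|. Ties in the single-best set go to the first feature in column
  order.
* **Order of operations**: within-subject normalization → subject split →
  |z| > 5 outlier drop → scaling by training statistics. Outlier removal
  therefore acts on the already-normalized features, on both partitions
  alike.

## Problem sizes used by the tests and the acceptance script

End-to-end checks run at a pilot scale chosen once: cohorts of 9 subjects
(6 train / 3 test after the 1/3 subject-wise split; ~250 training
sections), a 0.05-step threshold sweep, a 4-candidate grid
(C ∈ {2⁻⁵, 2⁻¹}, ε ∈ {2⁻³, 2⁻¹}), 5-fold CV and an electrode budget of 9,
over seeds 1…10. Recovery margins at this scale are wide enough that the
qualitative findings — every multivariate model beats the single-predictor
regression; under the electrode budget the RBF model beats the linear one
when the non-linear pathway dominates — reproduce in at least 8 of 10
seeds. The full powers-of-two grid, 10-fold CV and the 0.01-step sweep
remain the documented defaults for real analyses.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 9, seed = 1)
tab <- cohort_feature_table(cfg)
nf  <- normalize_within_subject(exclude_subjects(tab$features))
sp  <- split_by_subject(nf, 1/3, seed = 1)
ds  <- scale_by_training(remove_outlier_sections(sp$train),
                         remove_outlier_sections(sp$test))
scr  <- correlation_screen(ds)
sets <- build_threshold_sets(scr, step = 0.05)
fam  <- fit_model_family(ds, sets, screen = scr, electrode_budget = 9,
                         grid = default_grid(C = c(0.03125, 0.5),
                                             epsilon = c(0.125, 0.5)),
                         k_folds = 5, seed = 1)
report <- build_report(fam, ds, tab$annotations)
print(report)
plot(fam)   # CV MSE over the threshold sweep, both kernels
```

## Known limitations

* The correlation screen is computed on the full training partition before
  cross-validation — screening inside each fold is deliberately not done,
  since the threshold sweep defines the predictor sets once per training
  partition; at small
  training sizes this biases CV scores of junk-heavy low thresholds
  optimistically, and the best-CV threshold can sit below the
  held-out-optimal one. The effect shrinks with training size.
* Cross-validation folds ignore subject boundaries (row-level folds);
  fold scores therefore mix within-subject generalization with
  between-subject generalization, while the test partition measures only
  the latter.
* γ = 1/p is fixed, not searched; grids are user-overridable but the
  package provides no automatic grid refinement.
* The generator's artifact model is a single transient shape; the
  rejection rule is threshold-based and makes no attempt at correction
  (no ICA).
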