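---
title: "Methods: interpatient heart-beat classification with feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpatient heart-beat classification with feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbeats)
```

## The problem and its two defining constraints

Long-term ECG monitoring produces tens of thousands of beats per patient;
clinical review needs them sorted into the AAMI classes N (normal and
bundle-branch-block beats), S (supraventricular ectopic), V (ventricular
ectopic) and F (fusion). Two constraints shape every design choice in this
package:

1. **Interpatient evaluation.** In deployment there are no labeled beats
   from the tested patient, so training and test beats must come from
   disjoint patients. Morphology varies far more *between* patients than
   between classes within a patient; a protocol that mixes a patient's
   beats across the split produces optimistic, meaningless numbers. Every
   split, cross-validation fold, imputation statistic and histogram range
   in this package is computed on training patients only (the test suite
   contains an explicit poisoning test for this).
2. **Class unbalance.** Roughly 90% of beats are normal; F beats are under
   1%. Accuracy degenerates to majority prediction, so both classifiers
   carry per-class weights and evaluation uses the balanced classification
   rate (BCR).

## Models

**Weighted LDA.** Classes are modeled as Gaussians with a shared
covariance. With per-class weights $c_k$ the estimates are
$\mu_k = \frac{1}{N_k}\sum_{y_i=k} x_i$ and
$\Sigma = \sum_k c_k S_k \big/ \sum_k c_k N_k$ where $S_k$ is the
within-class scatter; prediction maximizes
$f_k(x) = -\tfrac12 \mu_k^\top \Sigma^{-1}\mu_k + \mu_k^\top \Sigma^{-1} x$.
With equal weights this is exactly the unweighted maximum-likelihood pooled
covariance — asserted to machine precision in the tests. The weighting
tilts $\Sigma$ toward the minority classes' scatter. Assumptions worth
stating: homoscedastic Gaussian classes and a linear boundary; both are
wrong for real beats, which is precisely why the SVM is the stronger model
and the LDA is reserved for the (cheap) wrapper search.

*Numerical choices.* If $\Sigma$ is singular (rank-deficient feature sets,
constant features), a ridge of `1e-8 * trace(Sigma)/p` is added — strongly
correlated features are the classical failure mode of LDA on large
ECG feature sets. Ties in the argmax go to the lowest class index, for
determinism.

**Weighted SVM.** Soft-margin SVM with the slack term split per class,
$c_{+1}\sum_{y_i=+1}\xi_i + c_{-1}\sum_{y_i=-1}\xi_i$: misclassifying a
minority beat costs more, which prevents the margin from collapsing onto
the majority class. Kernel fixed to polynomial $(x^\top z + 1)^d$;
multiclass by one-against-one voting with ties to the lowest class index.
The quadratic programs are solved by the libsvm backend in `e1071`
(per-class penalties via `class.weights`); the weighting contract is
validated in the tests by the equivalence of weighting and minority
oversampling, and by recall monotonicity in $c_k$. Degree $d \in 1..4$ and
$C \in 10^{-5}..10^{5}$ are searched by leave-one-patient-out
cross-validation on the training patients (44 grid points); ties prefer
the smaller degree, then the smaller $C$ — simpler models win draws.

Class weights default to the inverse class priors of the training labels,
normalized to sum to the number of classes. The normalization is irrelevant
for the LDA covariance (scale cancels) and folds into $C$ for the SVM; it
just keeps the two models' weight vectors on one scale. An optional
standardization switch (training mean/sd, default off at the model level)
exists because polynomial kernels on raw, heterogeneously scaled features
let large-range features dominate the inner product; the reference
pipeline enables it.

## Feature selection

**Histogram mutual information (filter).** $I(x;y) = H(y) - H(y\mid x)$
estimated by binning $x$ into $\lceil\sqrt{N}\rfloor$ equal-width bins over
its observed training range and plugging in empirical frequencies. Natural
logarithms; scores are in nats (the unit had to be fixed; nats make
$I \le H(y)$ comparisons direct). Small negative estimates from sampling
noise are clipped at zero; a constant feature has one effective bin and
scores exactly zero. The estimator is invariant under strictly monotone
affine transforms of $x$ (bins map bijectively), which the tests assert.
The plug-in estimator is biased upward on small samples — acceptable here
because it is only used to *rank* features against each other at a common
$N$. Ranking ties keep column order, so duplicated features resolve
deterministically. The default number of retained features is `k = 6`,
exposed as a parameter: the choice of "how many features are significantly
informative" from a sorted MI curve is a visual heuristic, and the package
deliberately makes no automatic elbow claim.

**Forward-backward wrapper.** Starting from the empty set, each forward
step adds the feature whose addition most increases the criterion; from the
third step on, a backward pass removes any previously selected feature
whose removal strictly increases it. The search stops when no addition
strictly improves or at `max_features = 10` (beyond ten features the
classifiers gain little and the search cost grows linearly). Strict (>)
improvement is required in both directions — this guarantees termination,
since each accepted step increases a bounded criterion.

The wrapper criterion is the BCR of the learner on an *internal*
patient-grouped split of the training data (25% of training patients held
out, seeded). A defensible alternative is training-set BCR; it was
rejected because a wrapper that scores on its own training fit reduces to
overfitting-driven selection, and scoring on the test patients would leak
the test set into model selection. The held-out-patients criterion keeps
the honest interpatient structure inside the search.

## The 249 features

Per lead (×2): 24 segmentation + 19 morphological + 20 Hermite + 30
higher-order-statistics + 21 normalized segmentation = 114. Shared: 4
reference R-R features, 4 detected R-R per lead, 3 normalized reference
R-R, 3 normalized detected R-R per lead. $2\times114 + 12 + 9 = 249$.
Column names are a function of the catalogue only, never of the data.

- **Segmentation (24).** QRS: flag, area, max, min, positive/negative
  area, sd, skewness, kurtosis, length, QR and RS lengths; P: flag, area,
  max, min, length; T: flag, area, max, min, length, QT and ST lengths.
  Areas are signed sums × sample period (mV·s), lengths in seconds. A
  wave's *flag* is 1 when its onset/offset pair was delineated — the
  convention that a flag reports detection success, which is the only
  reading under which boolean features are meaningful per beat. QT runs
  from QRS onset to T offset, ST from QRS offset (J point) to T onset.
- **R-R (12).** Previous and next interval, the mean of the up-to-10
  intervals formed by the 5 beats before and after (the most literal
  reading of "a window of 10 surrounding R spikes"; truncated at record
  edges, documented so it can be swapped), and the record mean. Boundary
  beats fall back to the record mean for the side they lack. Detected-
  annotation variants align each reference beat with the nearest detected
  spike so detector misses never drop a beat row.
- **Morphological (19).** 10 uniform samples of the amplitude from QRS
  onset to offset and 9 from QRS offset to T offset, endpoints included,
  linear interpolation between stored samples. Endpoint inclusion is a
  convention choice; including them keeps the features well defined even
  for degenerate one-sample windows.
- **Hermite (20).** The beat window (±250 ms around R) is projected onto
  orthonormal Hermite basis functions of orders 0–19 at width $\sigma$;
  $\sigma$ is picked from 30 geometrically spaced values in 5–100 ms (the
  span of physiological QRS widths, from narrow normal complexes to wide
  ventricular ones) to minimize RMS reconstruction error. Coefficients are
  computed by least squares on the sampled basis: identical to inner
  products when the sampled basis is orthonormal, and the correct discrete
  orthogonalization when window truncation at large $\sigma$/high order
  breaks exact orthonormality. Least squares also guarantees the nested-
  projection property (reconstruction error can only decrease with order),
  which the tests assert. All-zero beats get zero coefficients and the
  grid midpoint as $\sigma$.
- **Higher-order statistics (30).** Sample cumulant functions of order
  2–4 of the mean-removed window at 10 equally spaced lags in ±250 ms,
  diagonal slices for orders 3 and 4: $c_2(\tau)$ is the (biased, $1/N$)
  autocorrelation, $c_3(\tau) = \mathrm{E}[x_t x_{t+\tau}^2]$,
  $c_4(\tau) = \mathrm{E}[x_t x_{t+\tau}^3] - 3\,c_2(\tau)\,c_2(0)$.
  Because $c_2$ and $c_4$ are even in $\tau$, symmetric lags duplicate
  those values; the lag grid is kept symmetric anyway so the three orders
  share one grid.
- **Normalized groups (9 + 42).** R-R and segmentation features divided by
  their per-patient mean — heart rate and wave amplitude vary more between
  patients than between classes, and normalization removes exactly that
  nuisance. The record-mean R-R feature and the three flags are excluded
  (they normalize to constants); dropping the mean feature is also the
  only accounting under which the group sizes sum to 249. A zero patient
  mean makes the ratio undefined: the value becomes missing.

**Missingness.** Failed delineation, zero-variance moments and zero
normalization means produce missing values, never errors or sentinel
numbers. Missing entries are imputed with the patient's own mean of that
feature (test patients use only their own means — per-patient statistics
are causally clean), with a global-mean fallback; the pre-imputation mask
is kept for audit. After imputation every value is finite, asserted in the
tests.

## Filtering

Baseline wander is estimated per lead by two cascaded running medians (0.2 s
and 0.6 s windows — the first straddles QRS complexes, the second P/T
waves) and subtracted; the residual is low-pass filtered at 35 Hz with a
zero-phase (forward–backward) order-4 Butterworth. These defaults follow
the filtering lineage that established the interpatient protocol and are
flagged `per_ref_B3` in the pipeline configuration; exact taps of that
lineage are not published, so the parameters are exposed rather than
hard-coded. Medians use edge-truncated windows so the output length equals
the input length. The chain is close to idempotent (re-filtering changes
beat energy by under 5%) and its low-pass stage is linear, both asserted as
properties.

## The synthetic generator

Each beat is a sum of five Gaussian waves (P, Q, R, S, T). Class recipes:
N uses the patient template; S has normal morphology with the preceding
R-R shortened ×U(0.5, 0.8) and a compensatory pause; V has a widened QRS
(×U(1.8, 2.5)), no P wave, an inverted T, and is itself premature
(×U(0.45, 0.65), tighter coupling than S) with a compensatory pause —
premature ventricular contractions are premature by definition, and a
generator without V prematurity would misrepresent the single most
informative real-world feature (the previous R-R interval); F mixes the N
and V wave parameters 50/50 at normal timing. Default class prevalences
are 89.91 / 1.85 / 7.43 / 0.81% (N/S/V/F), the prevalences of the standard
ambulatory training corpus this protocol targets. Compensation is skipped
when the following beat is itself premature, so consecutive ectopics keep
their coupling intervals.

Each patient draws a heart rate (mean R-R ~ U(0.7, 1.0) s), a global
amplitude factor (U(0.85, 1.15)) and a per-wave template perturbation
(amplitudes ×U(0.75, 1.3), widths ×U(0.85, 1.2)); beats add a per-wave
amplitude jitter (sd 15%, the magnitude of respiration-driven modulation).
The per-patient template is what makes the interpatient problem nontrivial
here: raw morphology is only consistent *within* a patient, so patient
normalization has a real effect to detect, and timing features — which
normalize cleanly — carry the most transferable information, exactly the
structure seen in clinical data. White noise (default sd 0.05 mV) and a
0.25 Hz baseline sinusoid (default 0.10 mV) are added. Ground-truth
fiducials are the generative wave boundaries at ±3 sd (absent P for V
beats); each point is dropped independently at `missing_fiducial_rate` to
emulate delineation failures. "Detected" annotations jitter each R index
by ±1 sample with a 1% miss rate, independently per lead. Everything flows
from one seed; repeated simulation is byte-identical.

**What it does not emulate — and what passing tests therefore do not
show.** Real delineation errors are structured (systematically late onsets,
T-end ambiguity), not independent dropouts; real noise includes electrode
artifacts, muscle noise bursts and transient baseline jumps; rhythm
sequences (bigeminy, runs, atrial fibrillation) are absent because beats'
classes are drawn independently; morphology families (e.g. multiform
PVCs within one patient) are not modeled. Pipeline scores on this
generator validate the *machinery* — contracts, leakage-freedom,
weighting, selection behavior — not clinical performance. Numbers in the
90%+ BCR range on easy synthetic settings say nothing about real
recordings, where reported interpatient BCRs for this family of methods
are decades lower.

## Evaluation

BCR is the arithmetic mean of per-class recalls. The name "geometric mean"
is sometimes attached to this summary in the literature, but the defining
worked example — a majority-class predictor on four classes scoring 25% —
is only consistent with the arithmetic mean (a geometric mean would be 0
whenever any class is never recovered); the package therefore uses the
arithmetic form by default and provides `kind = "geometric"` for
completeness. An empty true class is an error by contract; a
cross-validation fold missing a class is scored over the classes it
contains and flagged in the search log.

## Problem sizes and runtimes

The shipped tests and examples run on deliberately modest sizes chosen as
the smallest that exercise every contract with stable statistics: cohorts
of 6–15 simulated patients × 120–300 beats for pipeline-level checks,
10 000 beats for prevalence bounds, 20–100 seeded repetitions for the
selection-recovery properties, and 1-point hyperparameter grids where the
grid search itself is not the property under test. The full 44-point
protocol grid with leave-one-patient-out folds is available through
`pipeline_config(grid = list(degrees = 1:4, costs = 10^(-5:5)))` and scales
linearly in grid size × patients.

## Known limitations

- The WFDB-style dialect covers two-lead format-212 records and the MIT
  binary annotation layout this package writes; anything else goes through
  the CSV dialect. No resampling between sampling rates is provided.
- Flat fiducial annotation streams cannot represent overlapping waves
  unambiguously: around very premature beats (R-on-T), a previous beat's T
  marks can fall beyond the next R spike and are then dropped on read,
  with a warning. The CSV dialect indexes fiducials by beat and does not
  have this limit.
- The MI filter scores features one at a time: it cannot see joint
  information or penalize redundancy (symmetric-lag cumulant duplicates
  rank adjacently). That is inherent to the univariate-ranking design.
- The wrapper is greedy; it is not guaranteed to find the optimal subset,
  only to terminate and never accept a non-improving step.
- Hyperparameter search cost is grid × patients × pairwise SVMs; on large
  cohorts the LOO-patient fold loop dominates the runtime.
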