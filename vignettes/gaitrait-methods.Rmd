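---
title: "From 2D gait keypoints to trait scores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 2D gait keypoints to trait scores: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrait)
```

## The measurement problem

Psychometric traits are usually measured by self-report questionnaires.
Gait — the whole-body dynamic pattern of walking — carries trait-relevant
information, and ordinary 2D video cameras make it cheap to record. The
pipeline in this package turns a few minutes of 25 Hz BODY25 keypoint
output (the 25-joint skeleton produced by off-the-shelf pose estimation,
each joint an `(x, y, confidence)` triple per frame) into a fixed-length
gait feature vector and regresses a trait score onto it. Everything
downstream of pose estimation is covered: preprocessing, feature
engineering, model fitting, cross-validated evaluation, split-half
reliability, and indicator-level weight analysis.

## Preprocessing

The analysis unit is a short, clean, fixed-length segment, produced in a
fixed order:

1. **Dropout interpolation.** Joints with detection confidence below
   `min_conf` (default 0.1) are linearly interpolated over time per
   channel; boundary gaps take the nearest valid value. A channel missing
   in more than half the frames aborts the participant — at that point
   interpolation would be invention. Both thresholds are deliberately
   conservative and exposed in the configuration.
2. **Face-toward selection.** Pose estimates are more accurate when the
   walker approaches the camera, so only approaching intervals are kept.
   No standard detection algorithm exists for this, so the package uses an
   apparent-size heuristic: the Neck-to-MidHip torso length, smoothed by a
   1 s moving average, grows while the walker approaches. The slope is
   estimated by a local linear regression over a ±2 s span (a
   Savitzky–Golay first derivative) and sub-second sign blips are bridged,
   so frame-level jitter cannot fragment an approach run. Sequences that
   carry explicit facing labels (e.g. from the simulator, or hand
   annotation) override the heuristic.
3. **MidHip re-referencing.** The MidHip (joint 8) coordinates are
   subtracted from every joint per frame, removing camera-relative
   position; the now identically-zero MidHip is dropped, leaving 24 joints
   (48 coordinate channels). The whole pipeline is therefore exactly
   translation-invariant, which the tests assert.
4. **Binomial smoothing.** Each channel is convolved with the 5-point
   binomial kernel `[1, 4, 6, 4, 1]/16`, a discrete Gaussian low-pass.
   The window is applied forward with no padding, so each pass shortens a
   channel by 4 frames; a centred alignment is available as a
   configuration flag but changes only a 2-frame phase. Smoothing runs
   after centering; because the centered MidHip is identically zero the
   order is immaterial for it.
5. **Length standardization.** The central contiguous 75 frames (3 s at
   25 Hz) are cropped out — no resampling, so native timing is preserved.
   A warning is emitted when the estimated cycle length implies fewer than
   4 gait cycles in the window. Cycle length is estimated as twice the lag
   of the first prominent positive autocorrelation peak (> 0.3) of the
   horizontal ankle-separation series, which peaks twice per stride.

A note on the 4-cycle rule: four cycles in a 3 s window require a stride
frequency of at least 4/3 Hz, which is brisk for normal walking. The
package warns rather than enforces, and the simulator's default stride
range (0.8–1.2 Hz) deliberately spans ordinary walking speeds, so the
warning is common and informative rather than fatal.

## The 2,472-dimensional feature vector

Four series families are computed per segment:

* **48 raw channels** — the smoothed, centered coordinates themselves;
* **48 difference channels** — first differences `Δf_k = f_{k+1} − f_k`,
  the per-frame motion;
* **26 distance channels** — 13 canonical joint pairs (head, upper-arm,
  arm, both-hand, thigh, leg, both-knee and stride swings), each
  contributing transverse `|x_a − x_b|` and longitudinal `|y_a − y_b|`
  distances. Per-axis absolute values are used because the quantities are
  distances; a signed version would be a different (and unordered)
  construct;
* **10 angle series** — angles at a vertex joint between two rays
  (neck tilt left/right, shoulders, elbows, hips, knees), computed as the
  arccosine of the clamped cosine, in radians within [0, π]. The hip
  angles use the contralateral hip as the vertex arm because the MidHip
  has been removed.

Ten summary statistics (maximum, minimum, mean, median, variance, root
mean square, skewness, kurtosis, absolute energy, coefficient of
variation) are taken over each series:
`48·10 + 48·10 + 26·10 + 10·10 = 1320` time-domain features. Estimator
conventions are frozen in code and tests: population variance (divisor
*n*), moment-based skewness `m₃/m₂^{3/2}` and excess kurtosis
`m₄/m₂² − 3` (both 0 for constant series), and `sd/mean` for the
variation coefficient (0 when `|mean| < 1e−12`).

Each of the 48 channels is also decomposed by a 5-level orthonormal Haar
wavelet transform into detail bands D1–D5 and the approximation A5, whose
per-band reconstructions sum exactly back to the source
(`X = D1 + D2 + D3 + D4 + D5 + A5`). Four statistics per band (absolute
maximum, mean, population variance, absolute energy) give
`48·6·4 = 1152` frequency-domain features; 2,472 in total.

Numerical choices for the wavelet step: orthonormal filters (`1/√2`) so
that Parseval's identity holds exactly on dyadic lengths and energy
features are interpretable; 75 is not dyadic, so odd-length levels are
extended by one sample with symmetric half-point padding (repeat the last
sample), which preserves perfect reconstruction — both properties are
asserted to 1e−10/1e−8 in the tests against an explicit-matrix oracle.

## Models, selection and evaluation

`trait_model()` z-scores the features (means and SDs from the fitting
data only; transform mode never refits), optionally runs sequential
forward selection, and fits one of seven regressors: ordinary least
squares (`lr`), a Gaussian process with RBF kernel and a white-noise term
floored at 1e−6 with target-mean normalization (`gp`), a 100-tree random
forest (`rfr`), and ε-SVR with linear, polynomial (degree 3), RBF and
sigmoid kernels (ε = 0.1, C = 1, kernel scale `1/(d·mean feature
variance)`). The constants are frozen defaults, exposed in the fitting
interface. Features whose sample SD is at or below 1e−8 are dropped
before scaling: structurally constant channels can carry O(1e−15)
floating-point dust that z-scoring would amplify into pure noise — and a
greedy selector will happily "discover" such noise.

Sequential forward selection greedily adds the feature that most improves
the pooled k-fold cross-validated Pearson correlation of out-of-fold
predictions with the score. A step must improve the score by at least
`tol = 0.02`; improvements below that are of the order of
fold-reassignment variability at n ≈ 150 and accepting them lets
selection climb into its own noise (we observed inner-CV scores exceeding
the attenuation ceiling implied by the generator's noise ratio, with
held-out extrapolation blow-ups from heavy-tailed statistics — the
stopping rule curbs exactly that). Ties break toward the smaller
canonical feature index, and the fold assignment is seeded, so selection
is fully deterministic. For `lr` the candidate scan is computed in closed
form via a bordered-Gram/Schur-complement update, scoring all 2,472
candidates per step with a handful of matrix products; a brute-force
refit oracle verifies the fast path in the tests.

`cross_validate()` evaluates the whole protocol: a seeded shuffled
k-fold partition (no stratification), per-fold standardization on the
training part, selection **inside each training fold** by default, fit,
and held-out prediction. Pooled out-of-fold predictions are scored once:
Pearson r overall and per subgroup, and MSE. Selection inside the folds
is the honest default because selecting on all data first leaks the
held-out fold into the choice of features; `paper_mode = TRUE` provides
that common protocol for comparability, and the test suite demonstrates
the leak on permuted traits (null mean r ≈ 0.28 under all-data selection
versus ≈ 0 nested). Correlation p-values use the t transform with n−2
degrees of freedom and are never used for selection.

## Reliability and weights

Odd–even split-half reliability treats the two frame parities of the
75-frame segment as parallel sub-tests: features are recomputed
independently on the 38-frame odd and 37-frame even halves (the same
extraction code path, asserted identical), both halves are predicted with
the unmodified full-segment model, and the reliability is the Pearson
correlation of the two prediction vectors across participants. Five
wavelet levels remain feasible because both halves keep at least 32
frames; the splitter requires 64 full frames.

For the linear model, each selected feature's absolute standardized
coefficient is aggregated to its source indicator (sum over features; a
per-indicator mean is available), with unselected indicators reported as
zero. The 13 distance aggregates are compared against the 10 angle
aggregates by a pooled-variance two-sample t-test — structurally df = 21
— with group SDs on the n−1 divisor.

## The synthetic walker

No public corpus of BODY25 walking bouts with trait scores exists, so the
package ships a generator that emulates the acquisition this pipeline
targets: 150 walkers, 2-minute bouts at 25 Hz, an approaching
(face-toward) first half and a receding second half, and trait scores
with sample mean 31.40 and SD 4.55 — the marginal moments typical of a
Rosenberg Self-Esteem Scale cohort.

Kinematics are a minimal sinusoidal limb model on a fixed-topology 2D
skeleton: antiphase thigh swings with a lagged knee-flexion term, arm
swing antiphase to the ipsilateral leg, head bob at twice the stride
frequency, and fixed offsets for eyes, ears, toes and heels. Approach is
modelled as isotropic apparent-scale growth (`approach_rate` per second)
— a perspective proxy sufficient for the size-trend facing heuristic, not
projective geometry. Per-walker parameters are drawn uniformly:
stride frequency 0.8–1.2 Hz, arm swing amplitude 0.15–0.55 rad, thigh
swing amplitude 0.25–0.55 rad; keypoint jitter is isotropic Gaussian with
SD 1 px by default against a 120 px hip-to-neck scale, and confidences
are uniform on (0.3, 1]. The trait is planted linearly in the two
amplitudes, `y = β₀ + β_arm·a_arm + β_leg·a_leg + ε` with ε Gaussian
(SD 0.08 against a linear-predictor SD of ≈ 0.16, implying an attenuation
ceiling of r ≈ 0.87), then affinely rescaled so the cohort sample moments
hit the targets exactly. The trait depends only on the amplitudes — never
on scale or approach rate — and the whole cohort is reproducible from one
seed.

What the simulator does *not* emulate: out-of-plane projection of
frontal-view leg motion, soft tissue and clothing dynamics, occlusions
(confidence dropouts are random, not biomechanical), pose-estimator bias,
and any nonlinear trait–gait coupling. Passing tests therefore show that
the machinery recovers a planted linear signal under periodic kinematics
and jitter — not that real trait–gait correlations of any particular size
exist.

## Protocol choices worth knowing about

* **Reliability surface.** When a model is selected on a *noiseless*
  cohort, hundreds of features tie at CV r ≈ 1 and the greedy selector's
  choice among them is effectively arbitrary; some ties (wavelet absolute
  maxima, medians, skewness) are sensitive to the frame-parity decimation
  and make split-half reliability erratic. The reliability analyses
  therefore train the model under the generator's default 1 px jitter —
  as with real recordings, noise steers selection toward robust features
  — and measure split-half agreement on noiseless deterministic walkers,
  which isolates the method's own internal consistency (observed r ≥
  0.99 across seeds; r collapses to ≈ 0 when the participant pairing is
  permuted, and degrades monotonically as jitter grows).
* **Problem sizes.** The test suite and acceptance script use cohorts of
  150 (recovery), 200 (null calibration and reliability), 60 (model
  training) and 30 (noise sweep) walkers, with 2-minute bouts where the
  acquisition protocol itself is under test and 20–60 s bouts elsewhere;
  the 75-frame analysis window never changes, so shorter bouts only
  shorten the search for an approach interval.
* **Open conventions.** The smoothing formula is implemented exactly as
  printed (forward window, length loss 4); whether smoothing precedes or
  follows centering is immaterial for the centered reference joint;
  frame parity is 1-based ("odd" = frames 1, 3, ...), which only relabels
  the halves; left/right semantic labels attached to distance indicators
  in the literature conflict with the BODY25 side convention — joint
  indices are authoritative throughout, labels are cosmetic.

## A worked example

```{r example, eval = FALSE}
library(gaitrait)

co <- simulate_cohort(cohort_config(n_walkers = 60, seed = 42))
X  <- extract_cohort_features(co$sequences)

ev <- cross_validate(X, co$traits$score, algorithm = "lr",
                     subgroups = co$traits$sex, seed = 1)
ev

model <- trait_model(X, co$traits$score, algorithm = "lr", seed = 1)
summary(model)
compare_indicator_groups(aggregate_weights(model))
```

## Known limitations

Single-person scenes only (the first detected person wins); no view
normalization, limb-length normalization or camera calibration beyond
MidHip centering; the facing heuristic assumes an approach produces a
monotone apparent-size trend; the seven regressors use frozen default
hyperparameters rather than tuned ones; and all empirical performance
statements in this vignette are about synthetic cohorts generated by the
package itself.
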