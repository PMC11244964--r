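---
title: "Methods: directional tuning and population decoding of 3D tongue kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional tuning and population decoding of 3D tongue kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(linguadir)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the synthetic generator does and does not emulate, and where genuinely open
design questions were settled.

## Coordinate frame and direction categories

All positions are tongue-tip marker coordinates in a cranial frame, origin
at the posterior nasal spine, in mm: x = posterior(−)/anterior(+),
y = left(−)/right(+), z = inferior(−)/superior(+). Trajectories are smoothed
with a zero-phase (forward–backward) 4th-order Butterworth low-pass filter
at 30 Hz; only the cutoff is a scientific parameter, the order is our
choice (4th is the field's default), and we pad with odd reflection before
filtering because a plain forward–backward pass with zero initial conditions
produces large edge transients on non-zero-mean signals.

Directional intervals come in two flavors. Feeding uses 100-ms tiles through
each gape cycle; drinking uses one 500-ms window (±250 ms) centered on each
minimum protrusion, where minimum protrusion is the local minimum of the
anteroposterior coordinate within a cycle (earliest frame on plateaus). A
window covers a fixed number of frames; its spike-counting span is the
half-open interval [t_start, t_start + span) and its displacement is
measured between the first and last frames inside the window, which makes a
1-s trace at 100-ms spans yield exactly 10 tiles and makes tiled spike
counts conserve total counts.

Every interval carries two angle families, both exposed because either
could feed a tuning analysis:

* the unsigned 3D angle between the start and end *position vectors*,
  θ = atan2(‖v₁×v₂‖, v₁·v₂) ∈ [0°, 180°];
* displacement-derived categories: the octant from the component signs of
  v₂ − v₁, the signed left-right angle of the horizontal projection
  (rightward positive, anterior = 0°), its half-open 10°-bins over
  [−30°, 30°) (bin k ⇔ angle ∈ [−30 + 10(k−1), −30 + 10k), so exactly six
  bins and a straight-ahead movement falls in bin 4), and yaw/pitch (yaw is
  identical to the left-right angle by construction; pitch is elevation
  above the horizontal plane).

Two numerical conventions worth noting: angles are snapped to nanodegrees
before binning so bin edges are decided by the intended angle rather than
floating-point rounding of `atan2`; and zero displacement components
tie-break toward the positive label (Ant, Sup, R), with an all-zero
displacement flagged degenerate and excluded from tuning inputs. The
standard anatomical-plane naming of the lateral and vertical sign
conventions is ambiguous in common usage; the package defines labels purely
by component signs, which is the operational content of any such mapping.

Balanced sampling (`balanced_interval_sample`) takes the per-direction
minimum count without replacement, seed-deterministically, so neural
analyses never see unequal direction frequencies.

Failed drinking cycles are endpoints deviating more than 2 SD (either tail)
from their spout's mean endpoint on any axis with nonzero spread. Note the
implication: with Gaussian endpoint scatter this rule flags roughly 12% of
clean cycles; it is a performance metric, not an outlier filter.

## Single-neuron directional statistics

**Modulation test.** The hypothesis is that mean firing-rate ranks are equal
across directions. We operationalize the bootstrap as a calibrated test: the
statistic is the spread (max − min) of per-direction mean mid-ranks on a
balanced design; its null distribution is built by resampling an equal
number of intervals per direction *from the rates pooled across directions*
(exchangeable under the null), 1000 replicates; a neuron is tuned when the
observed spread exceeds the null's 95th percentile. We first implemented
the alternative reading — per-direction percentile CIs of mean rank with a
pairwise-overlap decision — and measured its type-I error at 0.20 with
8 directions (28 pairwise comparisons at an uncorrected per-pair level); it
is not a level-α test, so the pooled-null form was adopted. The pooled-null
test measures type-I ≈ 0.05–0.07 at α = 0.05 and power ≈ 1.0 at
depth/baseline = 2 with 40 intervals per octant. Directions with fewer than
5 intervals yield an insufficient-data signal rather than a decision.

**Cosine tuning.** For neurons passing the modulation test, OLS of rate on
the components of each interval's *own* unit displacement (not octant
centroids — strictly more information, and it reduces to the grouped fit
when directions are discrete): rate ~ b₀ + bₓuₓ + b_yu_y + b_zu_z. The
full-regression F-test at p < 0.05 decides `fits_cosine` (computed directly
from RSS/TSS so noiseless fits do not trip `summary.lm` warnings); the PD
is the normalized coefficient vector. The directional index is the
depth-of-tuning of the fitted curve over the sphere,
DI = (f_max − f_min)/f_max with f_max = b₀ + ‖b‖ and f_min = b₀ − ‖b‖,
clipped to [0, 1]. This classical definition is one of several in use; it
is scale-invariant (multiplying all rates by c > 0 leaves it unchanged),
which the tests assert. Coplanar direction sets make the 3D fit
rank-deficient and are flagged rather than fit.

**Discrete PDs.** For three-spout (or six-bin) designs the PD is the
bootstrap modal direction: resample rates within each direction with
replacement, record the argmax-mean direction per replicate (ties uniform at
random), report the empirical distribution and its mode. On exchangeable
data the *expected* shares are 1/3 each, but any single dataset concentrates
on whichever direction drew the larger sample mean — the symmetry property
holds across datasets, not within one, and the tests check it accordingly.

**Fano factors.** FF = spike-count variance / mean per neuron; zero-mean
cells are excluded with a flag. The mean-matched variant bins per-neuron
mean counts into 20 equal-width bins over the common range, takes the
per-bin minimum histogram across groups, and averages each group's mean FF
over 50 random down-samples to that histogram (the bin count is our choice;
the procedure it mirrors does not fix one).

**Circular statistics.** No circular-statistics package is available in the
target environment, so the Rayleigh test (Z = nR̄² with the standard
finite-n corrected p) and the two-sample concentration k-test (the classical
F-ratio on (n − R), accurate for concentrated samples, R̄ ≳ 0.7) are
implemented directly; discrete PD distributions use `chisq.test`.

**Condition contrasts.** Neurons are matched by id across control and
nerve block; each is classified gained / lost / stable-tuned /
stable-untuned; tuned proportions are compared by chi-square and PD
distributions by the k-test. α = 0.05 two-sided throughout, with no
multiple-testing correction — matching the reporting conventions of the
analyses this package reimplements.

## Factor-Analysis population trajectories

Spike times are binned at 10 ms within trial windows of equal length and
smoothed within trial by a Gaussian kernel (SD 10 ms) truncated at ±3 SD and
column-renormalized, so each source bin's mass is conserved (no leakage
across trials; total per-trial counts preserved to 1e-6). Neurons under
1.0 spike/s are excluded before any fit.

The model is y ~ N(μ, C′C + R) with C (m × n) the loadings and R diagonal.
EM runs from a principal-axes initialization (eigenvectors of the ML
covariance, noise floor from the trailing eigenvalues) to a relative
log-likelihood tolerance of 1e-6 or 500 iterations; the trace is monotone
and returned. All E/M updates operate on the sample covariance, so the fit
cost is independent of the observation count. Unique variances are floored
at 1e-6 to avoid Heywood collapse.

Dimensionality is chosen by 3-fold cross-validated held-out log-likelihood
over a user grid, with seed-deterministic folds and ties going to the
smaller m; with no shared structure the held-out curve is flat-to-decreasing
and the smallest candidate wins.

Latents are extracted as posterior means E[z|y] = C(C′C + R)⁻¹(y − μ) — the
standard FA regression estimator — per trial, then averaged within
direction. The fitting itself is joint across directions (required for a
common latent space; fitting per direction would make trajectories
incomparable). Factors are ordered by shared variance explained via the SVD
of the loadings, and the reported cumulative explained variance is the
cumulative share of *shared* variance. Trial-averaging after latent
extraction (rather than extracting from trial-averaged data) preserves
distance statistics and is the recorded choice where the phrasing of the
source procedure is ambiguous.

Geometry: per 10-ms bin, the Euclidean distance over all m factors for each
unique direction pair (8 directions → 28 pairs; 3 → 3); path length is the
cumulative Euclidean distance travelled. Contrasts between conditions or
regions are two-sample t-tests on per-pair mean distances. Subsampling
controls rerun the pipeline on standardized trial counts (default 80 per
direction, 10 repeats) or on neuron-count-matched populations.

## Decoding

**KNN.** Euclidean K = 7 on per-interval rate vectors; each of 100
iterations draws 28 neurons (when more are available) and a stratified 80/20
split (stratification guarantees every class in training). Class-vote ties
break to the single nearest neighbor — a deterministic rule we fixed because
the reference implementation's behavior is unspecified. Features are raw
rates by default (`normalize = TRUE` z-scores on the training split). Chance
is 1/n_classes. The mixed-population protocol decodes a baseline full-MIo
population, then per iteration replaces 25 random MIo neurons with random
SIo neurons and reports the accuracy delta.

**LSTM sequence decoder.** A single-layer LSTM with a linear scalar readout,
trained by truncated BPTT and Adam with gradient clipping and L2 weight
decay, written in plain matrix code (no deep-learning framework is a
package dependency). The direction sequence (degrees; e.g. −45/0/+45 for
left/middle/right) is standardized for training and R² is computed on the
original scale, pooled over test steps per fold, then averaged over folds
and neuron groups (5 random groups of 28, drawn with replacement). Folds are
contiguous segments (default 25 intervals) so test steps are never
interleaved with training steps. Desk-scale defaults are hidden = 64,
epochs = 20; the headline configuration (400 hidden units, 50 epochs) is
available by argument. Weight decay defaults to 0.05: on inputs carrying no
directional signal it regularizes the network toward the mean predictor, so
shuffled-label R² sits near 0 instead of the strongly negative values an
unregularized network produces by overfitting noise; planted-signal R²
(≈ 0.97 on a well-tuned synthetic population) is essentially unaffected.
Because initialization, fold assignment and update order all run under one
seeded RNG, the protocol is exactly reproducible end-to-end — the decoding
result declares `deterministic = TRUE` rather than an optimizer
nondeterminism caveat.

## The synthetic generator: what it emulates, and what it does not

Feeding kinematics are a drift-plus-jitter walk: each 100-ms block draws an
octant from a configurable bias (default mildly favoring Anterior-Superior,
then Posterior-Inferior — the observed ordering of natural feeding; the
exact distribution of real movements is not published, so the bias is a free
parameter, not a claim about data) and drifts at 40 mm/s within it. Each
gape cycle restarts near a rest point; cycle length 0.5 s. Drinking licks
follow a raised-cosine protrusion profile from rest to an endpoint scattered
around the cued spout (per-axis SD = `noise_sd`, default 0.5 mm; spouts at
±~38° lateral and a 1-s lick period), giving well-defined minimum/maximum
protrusion events. Tuned neurons fire as inhomogeneous Poisson with
rate = max(0, baseline + depth·cos∠(movement, PD)) — the floor at zero
because Poisson rates must be nonnegative; a shared low-rank drive (for FA
validation) enters additively on the log rate through a stored loading
matrix, with per-trial latent states centered on direction-specific targets,
keeping rates positive and covariances FA-recoverable. The nerve block
scales tuning depth by `depth_scale`, inflates drinking endpoint SD by
`endpoint_sd_scale`, and rotates PDs about the vertical axis by
`pd_rotation_deg`; a sham block (all effects neutral) is bit-identical to
control.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: biomechanics (no tongue-shape, jaw or
food-interaction dynamics), history dependence and oscillatory firing
(PETH structure), non-cosine tuning shapes, electrode-level noise and
sorting artifacts, slow nonstationarities across a session, and realistic
correlations between kinematic richness and cycle type. Recovery results
validate the *estimators* under the assumed generative laws; they do not
certify effect sizes in real recordings, and the original study's headline
percentages depend on unreleased recordings and are out of reach by
construction.

## Problem sizes and calibration of the self-checks

The package's own validation (tests and `scripts/acceptance.R`) runs at
sizes chosen to give stable statistics on a single CPU: 200 null neurons ×
1000 bootstrap replicates for type-I calibration (empirically 0.03–0.07);
100 planted neurons × 400 balanced intervals for PD recovery (median error
≈ 6°, monotonically improving with interval count); FA subspace recovery at
10 000 observations (largest principal angle < 1°) with 20 cross-validation
replicates at 1200 observations (m = 3 recovered in ~100%); the nerve-block
contrast at 100 neurons per arm (tuned 71% → ~20%, mean inter-trajectory
distance ~1.5 → ~0.35 at depth_scale = 0.3). The KNN chance level is
estimated by averaging the 100-iteration mean accuracy over 10 independent
untuned 150-trial populations: chance is a property of the decoding
protocol, and a single 150-trial noise draw carries dataset-level
fluctuation of ±3–4 points that no number of split iterations removes.

## Known limitations

* The concentration k-test is an F-approximation valid for concentrated
  samples; diffuse PD distributions should rely on the chi-square route.
* The bootstrap modulation test assumes exchangeability of intervals under
  the null; strong within-cycle rate autocorrelation would make it
  anti-conservative. Balanced sampling across directions mitigates but does
  not remove this.
* FA assumes Gaussian observations; at very low counts (sub-spike bins) the
  model is misspecified, which is the usual practice it mirrors, not a bug —
  but dimension selection then tends conservative.
* The LSTM decoder is desk-scale; its absolute R² values are not comparable
  to a 400-unit/50-epoch configuration, only its calibration properties are
  asserted.
* The drinking feature-window question (100 ms at minimum protrusion for
  KNN vs ±250 ms for tuning) is left as two supported options
  (`make_intervals(span_ms = 100 or 500, anchor = "min_protrusion_centered")`);
  the package surfaces both rather than resolving which fed which analysis.
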