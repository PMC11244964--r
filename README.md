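# linguadir

Directional tuning and population decoding of 3D tongue kinematics in
orofacial sensorimotor cortex.

## The problem

During natural feeding and drinking, the tongue moves through a rich
repertoire of 3D directions. Neurons in the orofacial primary motor (MIo) and
somatosensory (SIo) cortices modulate their firing with the direction of
tongue-tip movement, much as arm-area motor cortex does for reaching.
`linguadir` is a tested, reusable R implementation of the full analysis chain
used to characterize that code:

1. **Kinematics.** Tongue-tip marker trajectories (200 Hz, cranial frame with
   the origin at the posterior nasal spine) are low-pass filtered
   (zero-phase 30 Hz Butterworth) and cut into directional intervals: 100-ms
   tiles through each feeding gape cycle, or ±250 ms windows around each
   minimum tongue protrusion during drinking. Each interval carries the 3D
   direction angle θ = atan2(‖v₁×v₂‖, v₁·v₂) between its start and end
   position vectors, an octant label from the displacement component signs
   (Ant/Post × Sup/Inf × L/R), a signed left-right angle with six half-open
   10°-bins over [−30°, 30°), and yaw/pitch.
2. **Single-neuron tuning.** A calibrated bootstrap test of directional
   modulation (spread of per-direction mean firing-rate ranks against a
   pooled-resampling null, 1000 replicates, α = 0.05); cosine tuning fits
   rate ~ b₀ + **b**·**u** with preferred direction PD = **b**/‖**b**‖ and
   directional index DI = (f_max − f_min)/f_max; bootstrap modal PDs for
   discrete (spout) directions; Fano factors with a mean-matched variant;
   Rayleigh, circular-concentration (k-) and chi-square tests on PD
   distributions; control vs nerve-block contrasts (gained/lost tuning,
   chi-square on tuned proportions).
3. **Population trajectories.** Factor Analysis y ~ N(μ, C′C + R) fitted by
   EM on 10-ms binned, Gaussian-smoothed spike counts (neurons under
   1 spike/s excluded), latent dimensionality selected by 3-fold
   cross-validated likelihood, trial-averaged latent trajectories per
   direction, per-bin inter-trajectory Euclidean distances (8 feeding
   directions → 28 pairs; 3 spouts → 3 pairs) and cumulative path lengths,
   plus equal-trial (N = 80 × 10 repeats) and equal-neuron subsampling
   controls.
4. **Decoding.** KNN classification of direction from per-interval firing
   rates (K = 7, stratified 80/20 splits, 100 iterations, 28-neuron
   subsamples, mixed MIo/SIo replacement protocol) and a compact LSTM
   sequence decoder (R² on the predicted direction sequence, 5-fold CV over
   random 28-neuron groups).
5. **Synthetic ground truth.** A generator that emulates the study's data:
   meandering feeding trajectories with configurable octant bias, rhythmic
   licks to three spouts, cosine-tuned Poisson neurons with planted PDs,
   optional low-rank shared log-rate drive, and a simulated sensory nerve
   block (tuning depth scaled down, endpoint scatter scaled up, PDs
   rotated). Every analysis is validated by parameter recovery against the
   planted truth.

## Worked example

```r
library(linguadir)

cfg <- synth_config("feeding", n_trials = 60, n_neurons = 40,
                    tuned_fraction = 0.7, baseline_rate = 10,
                    modulation_depth = 10, seed = 42)
kin <- generate_kinematics(cfg)
pop <- generate_population(cfg, kin)

ivb <- balanced_interval_sample(make_intervals(kin, span_ms = 100), seed = 42)
rt  <- interval_firing_rates(pop$spikes, ivb)
tuned <- tune_neurons(rt, n_boot = 1000, seed = 42)

bp  <- bin_and_smooth(pop$spikes, data.frame(t_start = ivb$t_start,
                                             t_end = ivb$t_end,
                                             label = ivb$label))
sel <- select_dimensionality(bp, 1:4, seed = 42)
fit <- fit_fa(bp, sel$m_star)
met <- trajectory_metrics(latent_trajectories(fit, bp))
dec <- knn_decode(rt, K = 7, iters = 100, subsample_n = 28, seed = 42)
```

This prints (reproducibly, seed 42):

```
tuned: 30/40 neurons (planted: 28)
median PD error over 27 cosine-tuned neurons: 9.7 deg
FA m* = 3
mean inter-trajectory distance over 28 pairs: 0.965
<decoding_result> knn: 0.3580 +/- 0.0827 (chance 0.1250, n=100)
```

That is: the bootstrap test recovers almost exactly the planted 28/40 tuned
neurons, cosine fits put recovered preferred directions within ~10° of the
planted ones at this (modest) trial count, cross-validation finds a
3-dimensional latent space, all 28 direction-pair trajectories separate, and
an 8-way KNN decode of movement octant runs at ~3× chance from 28 neurons
and 23 intervals per direction.

The simulated nerve block (`nerve_block = TRUE` with
`depth_scale = 0.3`) reduces the tuned fraction (e.g. 71% → 22% at 100
neurons, chi-square p ≈ 1e-11) and contracts the latent trajectory geometry
(mean inter-trajectory distance 1.51 → 0.37) — the qualitative signature of
deafferentation at the generator level.

A thin CLI wrapping the same functions ships at `inst/scripts/linguadir`
(subcommands `simulate | kinematics | tune | population | decode | run |
verify`).

## Scope

The package analyzes marker kinematics and spike timestamps; marker
reconstruction from video-radiography, spike sorting, and cross-session
waveform stability testing are upstream concerns (stability enters only as a
per-neuron flag). Real recordings from the original study are not publicly
deposited; the synthetic generator defines the study-like conditions under
which every method is validated.
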