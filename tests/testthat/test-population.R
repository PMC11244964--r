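test_that("binning places spikes and smoothing conserves per-trial counts", {
  spikes <- spike_dataset(
    data.frame(neuron_id = 1L, region = "MIo", spike_time_s = 0.055),
    neurons = data.frame(neuron_id = 1L, region = "MIo",
                         condition = "control", stable = TRUE),
    t_start = 0, t_end = 1)
  trials <- data.frame(t_start = 0, t_end = 0.1, label = "a")
  pop0 <- bin_and_smooth(spikes, trials, bin_ms = 10, smooth_sd_ms = 0,
                         min_rate = 0)
  expect_equal(as.numeric(pop0$counts[1, , 1]), c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  pop <- bin_and_smooth(spikes, trials, bin_ms = 10, smooth_sd_ms = 10,
                        min_rate = 0)
  expect_equal(sum(pop$smoothed[1, , 1]), 1, tolerance = 1e-6)
  expect_gt(pop$smoothed[1, 6, 1], pop$smoothed[1, 3, 1])
  # a near-edge spike still conserves mass (kernel renormalized at edges)
  spikes2 <- spike_dataset(
    data.frame(neuron_id = 1L, region = "MIo", spike_time_s = 0.004),
    neurons = spikes$neurons, t_start = 0, t_end = 1)
  pop2 <- bin_and_smooth(spikes2, trials, min_rate = 0)
  expect_equal(sum(pop2$smoothed[1, , 1]), 1, tolerance = 1e-6)
})

test_that("low-rate neurons are masked from the population fits", {
  s <- quick_session(n_trials = 30, n_neurons = 4, tuned_fraction = 0,
                     baseline_rate = 5, seed = 71)
  # neuron 5: one lonely spike in 15 s -> ~0.07 spikes/s, below 1.0
  sp <- s$spikes
  sp$spikes <- rbind(sp$spikes,
                     data.frame(neuron_id = 5L, region = "MIo",
                                spike_time_s = 1.0))
  sp$neurons <- rbind(sp$neurons,
                      data.frame(neuron_id = 5L, region = "MIo",
                                 condition = "control", stable = TRUE))
  iv <- balanced_interval_sample(make_intervals(s$kin, 100), seed = 1)
  pop <- bin_and_smooth(sp, data.frame(t_start = iv$t_start, t_end = iv$t_end,
                                       label = iv$label))
  expect_false(pop$include[["5"]])
  expect_true(all(pop$include[1:4]))
  Y <- linguadir:::pop_matrix(pop)
  expect_equal(ncol(Y), 4L)
})

test_that("EM fitting has monotone likelihood and recovers planted subspaces", {
  set.seed(13)
  m <- 3; n <- 15
  C <- matrix(rnorm(m * n), m, n)
  R <- runif(n, 0.3, 1); mu <- runif(n, 1, 4)
  Y <- simulate_fa_observations(mu, C, R, 4000, seed = 14)
  fit <- fit_fa(Y, m)
  expect_true(all(diff(fit$loglik) > -1e-7))   # EM monotonicity
  expect_true(all(fit$R > 0))
  expect_lt(max(principal_angles(fit$C, C)), 5)
  # model covariance reproduces the empirical covariance
  Sig <- crossprod(fit$C) + diag(fit$R)
  S <- cov(Y)
  expect_lt(norm(Sig - S, "F") / norm(S, "F"), 0.1)
  # null structure: diagonal data gives near-zero loadings
  Y0 <- matrix(rnorm(3000 * 8), 3000, 8)
  fit0 <- fit_fa(Y0, 2)
  expect_lt(sum(fit0$C^2) / sum(diag(cov(Y0))), 0.05)
  expect_error(fit_fa(Y, 20), "below the neuron count")
})

test_that("cross-validated dimensionality selection recovers the planted m", {
  set.seed(15)
  m <- 3; n <- 15
  C <- matrix(rnorm(m * n), m, n)
  hits <- vapply(1:8, function(i) {
    Y <- simulate_fa_observations(runif(n, 1, 3), C, runif(n, 0.3, 1), 1000,
                                  seed = 100 + i)
    select_dimensionality(Y, 1:5, folds = 3, seed = i)$m_star
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.8)
  # no shared structure: smallest grid value wins
  Y0 <- matrix(rnorm(1500 * 8), 1500, 8)
  expect_equal(select_dimensionality(Y0, 1:4, seed = 3)$m_star, 1L)
  # deterministic folds
  s1 <- select_dimensionality(Y0, 1:2, seed = 9)
  s2 <- select_dimensionality(Y0, 1:2, seed = 9)
  expect_identical(s1$folds, s2$folds)
  expect_identical(s1$cv, s2$cv)
})

test_that("latent trajectories separate planted directions and order factors", {
  s <- quick_session(n_trials = 60, n_neurons = 25, tuned_fraction = 0.8,
                     baseline_rate = 12, modulation_depth = 12,
                     latent_dim = 2, seed = 81)
  iv <- balanced_interval_sample(make_intervals(s$kin, 100), seed = 2)
  pop <- bin_and_smooth(s$spikes, data.frame(t_start = iv$t_start,
                                             t_end = iv$t_end,
                                             label = iv$label))
  fit <- fit_fa(pop, 3)
  set <- latent_trajectories(fit, pop)
  expect_equal(length(set$trajectories), 8L)
  # cumulative explained shared variance is increasing, concave ordering
  expect_true(all(diff(set$cum_expvar) >= -1e-12))
  expect_true(all(diff(diff(set$cum_expvar)) <= 1e-9))
  met <- trajectory_metrics(set)
  expect_equal(nrow(met$per_bin), 28L)    # 8 directions -> 28 pairs
  expect_true(all(met$mean_distance > 0))
  # duplicated direction labels give near-zero inter-trajectory distance
  pop_dup <- pop
  half <- seq_len(dim(pop$smoothed)[1])
  pop_dup$labels <- rep(c("d1", "d2"), length.out = length(pop$labels))
  # with labels assigned independently of direction, trajectories coincide
  set_dup <- latent_trajectories(fit, pop_dup)
  d_dup <- trajectory_metrics(set_dup)$mean_distance
  expect_lt(mean(d_dup), mean(met$mean_distance) / 3)
})

test_that("trajectory metrics are a proper geometry", {
  set.seed(17)
  fake <- structure(list(trajectories = list(
    a = matrix(rnorm(30), 10, 3), b = matrix(rnorm(30), 10, 3),
    c = matrix(rnorm(30), 10, 3))), class = "latent_trajectory_set")
  met <- trajectory_metrics(fake)
  d <- met$mean_distance
  expect_true(all(d >= 0))
  # triangle inequality on mean distances per bin
  pb <- met$per_bin
  expect_true(all(pb["a-b", ] + pb["b-c", ] >= pb["a-c", ] - 1e-12))
  # straight line: path length equals endpoint distance
  line <- structure(list(trajectories = list(
    u = outer(seq(0, 1, length.out = 10), c(1, 2, 2)),
    v = outer(seq(0, 1, length.out = 10), c(-1, 0, 1)))),
    class = "latent_trajectory_set")
  ml <- trajectory_metrics(line)
  expect_equal(unname(ml$path_length[["u"]]), sqrt(sum(c(1, 2, 2)^2)),
               tolerance = 1e-12)
  # homogeneity: scaling all latents by 2 doubles distances and lengths
  fake2 <- fake
  fake2$trajectories <- lapply(fake$trajectories, function(z) 2 * z)
  met2 <- trajectory_metrics(fake2)
  expect_equal(met2$mean_distance, 2 * met$mean_distance, tolerance = 1e-12)
  expect_equal(met2$path_length, 2 * met$path_length, tolerance = 1e-12)
})

test_that("subsampling controls reproduce full-data metrics on balanced data", {
  s <- quick_session(n_trials = 120, n_neurons = 15, tuned_fraction = 0.8,
                     baseline_rate = 12, modulation_depth = 12, seed = 91)
  iv <- balanced_interval_sample(make_intervals(s$kin, 100), seed = 3)
  pop <- bin_and_smooth(s$spikes, data.frame(t_start = iv$t_start,
                                             t_end = iv$t_end,
                                             label = iv$label))
  n_per <- min(table(pop$labels))
  full_fit <- fit_fa(pop, 2)
  full_set <- latent_trajectories(full_fit, pop)
  full_d <- mean(trajectory_metrics(full_set)$mean_distance)
  ctl <- subsample_controls(pop, "equal_trials", m = 2,
                            n_trials = n_per - 2, repeats = 4, seed = 5)
  expect_equal(nrow(ctl), 4L)
  expect_lt(abs(mean(ctl$mean_distance) - full_d) / full_d, 0.25)
  # equal_neurons with the same population twice: similar distributions
  ctl2 <- subsample_controls(pop, "equal_neurons", m = 2, pop2 = pop,
                             repeats = 3, seed = 6)
  expect_equal(nrow(ctl2), 6L)
  d1 <- ctl2$mean_distance[ctl2$population == 1]
  d2 <- ctl2$mean_distance[ctl2$population == 2]
  expect_lt(abs(mean(d1) - mean(d2)) / mean(c(d1, d2)), 0.3)
  expect_error(subsample_controls(pop, "equal_trials", m = 2,
                                  n_trials = 10 * n_per),
               "insufficient trials")
})
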